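test_that("ladder rungs hypothesize sizes between the configured bounds", {
  # one rung must sit at 32/(3.2/0.1) = 1 when 3.2 cm is on the size grid
  cfg <- ladder_config(n_rungs = 2, min_size_cm = 1.0, max_size_cm = 5.5)
  expect_equal(build_ladder(cfg, 0.1), sort(c(32 / 55, 3.2)))
  cfg16 <- ladder_config()
  ladder <- build_ladder(cfg16, 0.1)
  expect_length(ladder, 16)
  expect_true(!is.unsorted(ladder))
  ratios <- ladder[-1] / ladder[-16]
  expect_equal(ratios, rep(ratios[1], 15), tolerance = 1e-9)
  # geometric grid: hypothesized size 3.2 cm maps to magnification 1
  cfg2 <- ladder_config(n_rungs = 3, min_size_cm = 1.6, max_size_cm = 6.4)
  expect_equal(build_ladder(cfg2, 0.1)[2], 1)
  expect_error(ladder_config(n_rungs = 1), class = "lesionruler_parameter_error")
  expect_error(build_ladder(cfg16, -0.1), class = "lesionruler_parameter_error")
})

test_that("the oracle probability sequence steps at the canonical magnification", {
  case <- fixture_circle_case()           # 3.2 cm at 0.1 cm/px -> flip at m = 1
  ladder <- build_ladder(ladder_config(), 0.1)
  probs <- classify_ladder(case, case$seed_point, ladder, phantom_oracle(case))
  expect_length(probs, 16)
  expect_equal(probs, as.numeric(ladder * 32 > 32))
  expect_error(classify_ladder(case, c(-3, 5), ladder, phantom_oracle(case)),
               class = "lesionruler_parameter_error")
})

test_that("flip estimation interpolates a clean step at the geometric mean", {
  ladder <- exp(seq(log(0.5), log(2), length.out = 6))
  flip <- estimate_flip(ladder, c(0, 0, 0, 1, 1, 1))
  expect_equal(flip$flip_magnification, sqrt(ladder[3] * ladder[4]), tolerance = 1e-12)
  expect_equal(flip$monotone_violations, 0)
  expect_true(is.na(flip$out_of_range))

  all_large <- estimate_flip(ladder, rep(1, 6))
  expect_equal(all_large$flip_magnification, ladder[1])
  expect_equal(all_large$out_of_range, "above_range")
  all_small <- estimate_flip(ladder, rep(0, 6))
  expect_equal(all_small$flip_magnification, ladder[6])
  expect_equal(all_small$out_of_range, "below_range")

  noisy <- estimate_flip(ladder, c(0, 1, 0, 1, 1, 1))
  expect_equal(noisy$monotone_violations, 1)
})

test_that("isotonic flip placement matches the exhaustive monotone-step oracle", {
  set.seed(2024)
  for (rep_i in 1:200) {
    n <- sample(2:12, 1)
    ladder <- exp(seq(log(0.4), log(2.5), length.out = n))
    probs <- switch(sample(3, 1),
      round(runif(n)),                                   # noisy hard labels
      runif(n),                                          # arbitrary probabilities
      pmin(1, pmax(0, plogis(3 * (seq_len(n) - n / 2)) + rnorm(n, 0, 0.2))))
    fit_oracle <- brute_force_isotonic(probs)
    est <- estimate_flip(ladder, probs)
    expect_equal(est$fit, fit_oracle, tolerance = 1e-9)
    expect_equal(est$flip_magnification, crossing_from_fit(ladder, fit_oracle),
                 tolerance = 1e-9)
  }
})

test_that("monotone probabilities reduce the isotonic fit to first-crossing detection", {
  ladder <- exp(seq(log(0.5), log(2), length.out = 10))
  probs <- c(0, 0, 0.1, 0.2, 0.4, 0.6, 0.9, 1, 1, 1)
  est <- estimate_flip(ladder, probs)
  expect_equal(est$fit, probs)   # isotonic is a no-op on monotone input
  i <- max(which(probs < 0.5))
  x <- log(ladder)
  xstar <- x[i] + (0.5 - probs[i]) / (probs[i + 1] - probs[i]) * (x[i + 1] - x[i])
  expect_equal(est$flip_magnification, exp(xstar), tolerance = 1e-12)
})

test_that("measurement satisfies the flip identity and recovers phantom truth", {
  case <- synthesize_lesion(phantom_spec("spiculated", 2.7, pixel_spacing_cm = 0.08,
                                         spiculation_count = 7,
                                         spiculation_length_frac = 0.2, rng_seed = 31))
  res <- measure_lesion(case, clf = phantom_oracle(case))
  expect_equal(res$size_cm * res$flip_magnification / res$spacing_cm, 32,
               tolerance = 1e-9)
  expect_lt(abs(res$size_cm - 2.7) / 2.7, 0.01)
  expect_length(res$rung_probs, 16)

  coarse <- measure_lesion(case, clf = phantom_oracle(case),
                           config = ladder_config(refine = FALSE))
  step <- (5.5 / 1.0)^(1 / 15)
  expect_lt(abs(log(coarse$size_cm / 2.7)), log(step) / 2 + 1e-9)
})

test_that("measurement is robust to the choice of interior seed point", {
  case <- synthesize_lesion(phantom_spec(true_diameter_cm = 3.8, aspect_ratio = 0.75,
                                         rotation_deg = 40, rng_seed = 17))
  res1 <- measure_lesion(case, clf = phantom_oracle(case))
  interior <- which(case$mask, arr.ind = TRUE) - 1L
  set.seed(5)
  alt <- interior[sample(nrow(interior), 1), ]
  res2 <- measure_lesion(case, seed = alt, clf = phantom_oracle(case))
  expect_lt(abs(res1$size_cm - res2$size_cm) / res1$size_cm, 0.02)
})

test_that("measurements are scale-equivariant across pixel spacings", {
  for (sp in c(0.05, 0.1)) {
    case <- synthesize_lesion(phantom_spec(true_diameter_cm = 3.0, aspect_ratio = 1,
                                           pixel_spacing_cm = sp, rng_seed = 8))
    res <- measure_lesion(case, clf = phantom_oracle(case))
    expect_lt(abs(res$size_cm - 3.0) / 3.0, 0.01)
  }
})

test_that("lesions outside the hypothesized range are flagged, not silently measured", {
  case <- synthesize_lesion(phantom_spec(true_diameter_cm = 3.0, rng_seed = 9))
  # pretend the lesion is 0.5 cm: every rung sees it as SMALLER
  tiny_oracle <- oracle_classifier(function(f) f$magnification * 5)
  res <- measure_lesion(case, clf = tiny_oracle)
  expect_equal(res$out_of_range, "below_range")
  big_oracle <- oracle_classifier(function(f) f$magnification * 500)
  res2 <- measure_lesion(case, clf = big_oracle)
  expect_equal(res2$out_of_range, "above_range")
})

test_that("anisotropic slices are squared up before measurement", {
  case <- synthesize_lesion(phantom_spec(true_diameter_cm = 3.0, aspect_ratio = 1,
                                         pixel_spacing_cm = 0.1, rng_seed = 23))
  # stretch columns 2x: simulate 0.1 x 0.05 spacing
  stretched <- resample_bicubic(case$image + 0, c(1, 2))
  sl <- ct_slice(stretched, spacing_cm = c(0.1, 0.05),
                 window_center = -600, window_width = 1500, source_id = "aniso")
  seed <- c(case$seed_point[1], 2 * case$seed_point[2])
  # analytic oracle for the squared-up geometry: M_px = 3.0 cm / 0.05 cm/px
  oracle <- oracle_classifier(function(f) f$magnification * 60)
  res <- measure_lesion(sl, seed = seed, clf = oracle)
  expect_equal(res$spacing_cm, 0.05)
  expect_lt(abs(res$size_cm - 3.0) / 3.0, 0.01)
})
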