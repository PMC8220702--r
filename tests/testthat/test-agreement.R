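test_that("percent difference follows the symmetric formula and is antisymmetric", {
  expect_equal(percent_difference(3, 3), 0)
  expect_equal(percent_difference(2, 1), 200 / 3)
  set.seed(1)
  a <- runif(50, 0.5, 6); b <- runif(50, 0.5, 6)
  expect_equal(percent_difference(a, b), -percent_difference(b, a))
  expect_true(all(abs(percent_difference(a, b)) < 200))
  expect_error(percent_difference(-1, 0.5), class = "lesionruler_parameter_error")
})

test_that("Bland-Altman limits are mean +/- 1.96 sample SD", {
  same <- bland_altman(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$mean_pct_diff, 0)
  expect_equal(same$sd_pct_diff, 0)
  expect_equal(unname(same$loa), c(0, 0))
  expect_length(same$outside_indices, 0)

  # construct pairs whose percent differences are exactly -1, 0, +1
  h <- c(2, 2, 2)
  d <- c(-1, 0, 1)
  dl <- h * (200 + d) / (200 - d)
  ba <- bland_altman(dl, h)
  expect_equal(ba$mean_pct_diff, 0, tolerance = 1e-12)
  expect_equal(ba$sd_pct_diff, 1, tolerance = 1e-12)
  expect_equal(unname(ba$loa), c(-1.96, 1.96), tolerance = 1e-12)
  expect_length(ba$outside_indices, 0)
  expect_error(bland_altman(2, 2), class = "lesionruler_insufficient_data")
})

test_that("LOA internal identity holds on arbitrary data", {
  set.seed(7)
  dl <- runif(40, 1, 5); h <- runif(40, 1, 5)
  ba <- bland_altman(dl, h)
  expect_equal(unname(ba$loa),
               ba$mean_pct_diff + c(-1.96, 1.96) * ba$sd_pct_diff)
})

test_that("pixel differences convert to percent via spacing and size", {
  expect_equal(pixel_difference_percent(5, 0.1, 5), 10)
  expect_equal(pixel_difference_percent(5, 0.1, 2), 25)
  expect_equal(pixel_difference_percent(0, 0.07, 3.3), 0)
  expect_error(pixel_difference_percent(5, 0, 2), class = "lesionruler_parameter_error")

  px <- mean_pixel_difference(c(3.1, 2.2, 4.05), c(3.0, 2.3, 4.05), 0.1)
  expect_equal(px$mean_px, mean(c(1, 1, 0)))
  uniform <- mean_pixel_difference(c(3.1, 2.1, 1.1), c(3.0, 2.0, 1.0), 0.1)
  expect_equal(uniform$mean_px, 1, tolerance = 1e-9)
  expect_equal(uniform$sd_px, 0, tolerance = 1e-9)
  signed <- mean_pixel_difference(c(3.1, 2.9), c(3.0, 3.0), 0.1, signed = TRUE)
  expect_equal(signed$mean_px, 0, tolerance = 1e-9)
})

test_that("ICC(2,1) matches an independent ANOVA computation", {
  set.seed(42)
  for (i in 1:25) {
    m <- matrix(rnorm(20, mean = 3), 10, 2)
    res <- icc_two_way_random(m)
    expect_equal(res$icc, icc21_via_aov(m), tolerance = 1e-10)
  }
  # identical columns with non-constant rows: perfect agreement
  m <- cbind(1:5, 1:5)
  expect_equal(icc_two_way_random(m)$icc, 1)
  # large constant rater bias with near-constant targets: near zero
  m2 <- cbind(rnorm(5, 10, 0.01), rnorm(5, 10, 0.01) + 100)
  expect_lt(icc_two_way_random(m2)$icc, 0.01)
  # degenerate all-identical matrix
  deg <- icc_two_way_random(matrix(3, 4, 2))
  expect_equal(deg$icc, 1)
  expect_true(deg$degenerate)
})

test_that("ICC is invariant to common shifts and positive scalings", {
  set.seed(3)
  m <- matrix(rnorm(30, 5), 15, 2)
  base <- icc_two_way_random(m)$icc
  expect_equal(icc_two_way_random(m + 11.3)$icc, base, tolerance = 1e-12)
  expect_equal(icc_two_way_random(m * 2.7)$icc, base, tolerance = 1e-12)
})

test_that("the ICC confidence interval matches an external reference", {
  # 10x2 fixture; reference interval computed once with pingouin's ICC2
  # (two-way random effects, absolute agreement, single rater)
  m <- matrix(c(3.2, 2.1, 4.5, 1.8, 2.9, 3.7, 4.1, 2.5, 3.3, 1.9,
                3.4, 2.0, 4.4, 2.0, 3.1, 3.5, 4.3, 2.4, 3.6, 2.1),
              ncol = 2)
  res <- icc_two_way_random(m)
  expect_equal(res$icc, 0.978912, tolerance = 1e-5)
  expect_equal(unname(res$ci[1]), 0.92, tolerance = 5e-3)
  expect_equal(unname(res$ci[2]), 0.99, tolerance = 5e-3)
  expect_true(res$ci[1] < res$icc && res$icc < res$ci[2])
})

test_that("Bonferroni pairwise comparison counts, adjusts, and skips correctly", {
  set.seed(11)
  groups <- setNames(lapply(1:6, function(i) rnorm(20)), LETTERS[1:6])
  out <- bonferroni_pairwise(groups)
  expect_equal(nrow(out), choose(6, 2))
  expect_true(all(out$adjusted_p >= out$raw_p - 1e-15))
  expect_true(all(out$adjusted_p <= 1))
  expect_equal(out$adjusted_p, pmin(1, out$raw_p * 15))

  shifted <- list(A = rnorm(20), B = rnorm(20) + 3)
  expect_true(bonferroni_pairwise(shifted)$significant)

  short <- list(A = rnorm(10), B = rnorm(10), C = 1)
  expect_warning(out2 <- bonferroni_pairwise(short),
                 class = "lesionruler_group_skipped")
  expect_equal(nrow(out2), 1)
  expect_error(suppressWarnings(bonferroni_pairwise(list(A = rnorm(5), B = 1))),
               class = "lesionruler_insufficient_data")
})

test_that("the agreement report assembles all statistics consistently", {
  cases <- sample_phantom_dataset(30, master_seed = 77)
  pairs <- simulate_measurement_pairs(cases, sd_pct_human = 2, sd_pct_dl = 2,
                                      rng_seed = 5)
  rep <- agreement_report(pairs)
  expect_gt(rep$icc, 0.9)
  expect_equal(unname(rep$loa),
               rep$mean_pct_diff + c(-1.96, 1.96) * rep$sd_pct_diff)
  expect_equal(rep$n, 30)
  expect_true(rep$n_outside_loa >= 0 && rep$n_outside_loa <= rep$n)
  expect_s3_class(rep$group_comparison, "data.frame")
  expect_output(print(rep), "ICC")

  # injected group bias is detectable by the pairwise comparison
  biased <- simulate_measurement_pairs(
    sample_phantom_dataset(120, master_seed = 78),
    sd_pct_human = 2, sd_pct_dl = 2,
    bias_pct_by_group = c(B = 12), rng_seed = 6)
  rep2 <- agreement_report(biased)
  sig <- rep2$group_comparison[rep2$group_comparison$significant, ]
  expect_true(any(sig$group_i == "B" | sig$group_j == "B"))
})
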