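test_that("pixel conversion and canonical magnification obey their identities", {
  expect_equal(cm_to_pixels(3.2, 0.1), 32)
  expect_equal(cm_to_pixels(5.0, 0.1), 50)
  expect_equal(cm_to_pixels(1.0, 0.05), 20)
  expect_equal(canonical_magnification(32), 1)
  expect_equal(canonical_magnification(64), 0.5)
  expect_equal(canonical_magnification(16), 2)
  expect_error(cm_to_pixels(-1, 0.1), class = "lesionruler_parameter_error")
  expect_error(canonical_magnification(0), class = "lesionruler_parameter_error")
  # round trip: magnifying M_px by 32/M_px gives exactly 32 apparent pixels
  for (d in c(0.7, 1.9, 3.21, 5.44)) {
    for (s in c(0.051, 0.1, 0.137)) {
      m <- cm_to_pixels(d, s)
      expect_equal(canonical_magnification(m) * m, 32, tolerance = 1e-12)
    }
  }
})

test_that("bicubic resampling scales dimensions and preserves distances", {
  img <- matrix(runif(200 * 200), 200)
  expect_identical(dim(resample_bicubic(img, 1)), c(200L, 200L))
  expect_identical(dim(resample_bicubic(img, 0.5)), c(100L, 100L))
  expect_identical(dim(resample_bicubic(img, c(0.5, 1.5))), c(100L, 300L))
  expect_error(resample_bicubic(img, 0.001), class = "lesionruler_parameter_error")
})

test_that("a resampled disc has the expected mask diameter", {
  # disc of diameter 40 px at magnification 0.8 -> 32 px, checked by
  # thresholding and brute-force longest chord
  n <- 200
  dr <- matrix(seq_len(n) - (n + 1) / 2, n, n)
  img <- (dr^2 + t(dr)^2 <= 20^2) * 1.0
  out <- resample_bicubic(img, 0.8)
  expect_lt(abs(mask_longest_chord_px(out > 0.5) - 32), 1)
})

test_that("crop geometry: interior crops, corner padding, center mapping", {
  img <- matrix(seq_len(512 * 512) / (512 * 512), 512)
  mid <- crop_frame(img, c(255, 255))
  expect_identical(dim(mid), c(128L, 128L))
  expect_equal(mid[65, 65], img[256, 256])  # 0-based center -> index (64,64)
  expect_equal(mid, img[192:319, 192:319])

  corner <- crop_frame(img, c(0, 0), fill = -1)
  expect_true(all(corner[1:64, ] == -1))
  expect_true(all(corner[, 1:64] == -1))
  expect_equal(corner[65:128, 65:128], img[1:64, 1:64])

  const <- crop_frame(matrix(7, 300, 300), c(10, 150), fill = 0)
  expect_true(all(const %in% c(0, 7)))
  expect_error(crop_frame(img, c(-1, 10)), class = "lesionruler_parameter_error")
})

test_that("crop is translation-consistent away from borders", {
  img <- matrix(runif(400 * 400), 400)
  a <- crop_frame(img, c(200, 200))
  b <- crop_frame(img, c(210, 195))
  expect_equal(a[31:110, 41:120], b[21:100, 46:125])
})

test_that("resample-then-crop equals the direct frame extraction", {
  case <- fixture_circle_case()
  image <- apply_window(as_ct_slice(case))
  for (m in c(0.7, 1.0, 1.6)) {
    mapped <- sign(m * (case$seed_point + 0.5) - 0.5) *
      floor(abs(m * (case$seed_point + 0.5) - 0.5) + 0.5)
    full <- crop_frame(resample_bicubic(image, m), mapped, fill = 0)
    direct <- extract_frame(image, case$seed_point, m)$patch
    expect_equal(direct, full, tolerance = 1e-12)
  }
})

test_that("training frames carry labels consistent with the resampled mask", {
  case <- fixture_circle_case()
  policy <- augmentation_policy(max_shift_px = 8L, per_image_count = 18L,
                                balance = FALSE)
  frames <- prepare_training_frames(case, policy = policy, rng_seed = 3)
  expect_gt(length(frames), 0)
  for (f in frames) {
    expect_identical(dim(f$patch), c(128L, 128L))
    expect_equal(f$apparent_size_px, f$zoom * 32, tolerance = 1e-12)
    expect_gte(abs(f$apparent_size_px - 32), policy$exclusion_band_px)
    # oracle: resample the noiseless mask at the frame magnification and
    # re-measure its longest chord
    chord <- mask_longest_chord_px(resample_bicubic(case$mask * 1, f$magnification) > 0.5)
    expect_equal(f$label, if (chord > 32) "LARGER" else "SMALLER")
  }
})

test_that("the exclusion band drops boundary frames", {
  case <- fixture_circle_case()
  policy <- augmentation_policy(zoom_factors = 1, per_image_count = 1L,
                                max_shift_px = 0L, balance = FALSE,
                                exclusion_band_px = 0.5)
  expect_warning(frames <- prepare_training_frames(case, policy = policy),
                 class = "lesionruler_empty_frames")
  expect_length(frames, 0)
  # zoom 1.25 -> apparent 40 px, labeled LARGER
  policy2 <- augmentation_policy(zoom_factors = 1.25, per_image_count = 1L,
                                 max_shift_px = 0L, balance = FALSE)
  f <- prepare_training_frames(case, policy = policy2)[[1]]
  expect_equal(f$apparent_size_px, 40)
  expect_equal(f$label, "LARGER")
})

test_that("balancing yields exactly equal class counts on skewed inputs", {
  case <- fixture_circle_case()
  # skewed zoom grid: 3 smaller, 9 larger
  policy <- augmentation_policy(zoom_factors = c(0.6, 0.7, 0.8, seq(1.1, 1.9, 0.1)),
                                per_image_count = 12L, balance = TRUE,
                                max_shift_px = 4L)
  frames <- prepare_training_frames(case, policy = policy, rng_seed = 11)
  labs <- table(vapply(frames, `[[`, "", "label"))
  expect_equal(unname(labs["SMALLER"]), unname(labs["LARGER"]))
  expect_equal(sum(labs), 6)
})

test_that("frame-set writer produces a complete manifest", {
  case <- fixture_circle_case()
  frames <- prepare_training_frames(case,
    policy = augmentation_policy(per_image_count = 6L, max_shift_px = 4L,
                                 balance = FALSE), rng_seed = 2)
  dir <- withr::local_tempdir()
  manifest <- write_frame_set(frames, dir)
  expect_equal(nrow(manifest), length(frames))
  expect_true(all(file.exists(manifest$path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
})
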