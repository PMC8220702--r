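test_that("ground-truth diameter and endpoints are exact for analytic shapes", {
  circle <- fixture_circle_case()
  expect_equal(circle$true_diameter_cm, 3.2)
  expect_equal(sqrt(sum(diff(circle$true_endpoints)^2)), 32, tolerance = 1e-9)

  rot <- synthesize_lesion(phantom_spec(true_diameter_cm = 2, aspect_ratio = 0.5,
                                        rotation_deg = 90, pixel_spacing_cm = 0.1,
                                        rng_seed = 2))
  ep <- rot$true_endpoints
  expect_equal(sqrt(sum(diff(ep)^2)) * rot$spacing_cm, 2, tolerance = 1e-9)
  # major axis at 90 degrees runs along image rows
  expect_equal(abs(diff(ep[, 2])), 0, tolerance = 1e-6)
})

test_that("mask longest chord matches the brute-force boundary oracle for every family", {
  specs <- list(
    phantom_spec("smooth_ellipse", 3.1, aspect_ratio = 0.7, rotation_deg = 35, rng_seed = 11),
    phantom_spec("spiculated", 4.0, spiculation_count = 8,
                 spiculation_length_frac = 0.25, rotation_deg = 120, rng_seed = 12),
    phantom_spec("adjacent_pair", 4.5, rotation_deg = 60, rng_seed = 13),
    phantom_spec("central_density", 2.6, aspect_ratio = 0.85, rng_seed = 14))
  for (sp in specs) {
    case <- synthesize_lesion(sp)
    chord_px <- mask_longest_chord_px(case$mask)
    true_px <- case$true_diameter_cm / case$spacing_cm
    expect_lt(abs(chord_px - true_px), sqrt(2),
              label = sprintf("%s chord error (px)", sp$shape_family))
  }
})

test_that("seed point lies strictly inside the lesion mask", {
  for (seed in 1:5) {
    case <- synthesize_lesion(phantom_spec("adjacent_pair", 3.5, rng_seed = seed))
    expect_true(case$mask[case$seed_point[1] + 1, case$seed_point[2] + 1])
  }
})

test_that("adjacent-pair lobes are each strictly shorter than the union diameter", {
  case <- synthesize_lesion(phantom_spec("adjacent_pair", 4.0, rng_seed = 21))
  # chord confined to the seed lobe: restrict the mask to pixels nearer the
  # seed-side endpoint than the far endpoint's lobe
  cc <- which(case$mask, arr.ind = TRUE) - 1L
  d1 <- sqrt((cc[, 1] - case$true_endpoints[1, 1])^2 + (cc[, 2] - case$true_endpoints[1, 2])^2)
  lobe1 <- cc[d1 < 0.66 * 4.0 / case$spacing_cm, , drop = FALSE]
  hull <- grDevices::chull(lobe1[, 1], lobe1[, 2])
  pts <- lobe1[hull, , drop = FALSE]
  dd <- sqrt(max(outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2))
  expect_lt(dd * case$spacing_cm, case$true_diameter_cm)
})

test_that("synthesis is deterministic given the seed and distinct otherwise", {
  a <- synthesize_lesion(phantom_spec(true_diameter_cm = 3, rng_seed = 5))
  b <- synthesize_lesion(phantom_spec(true_diameter_cm = 3, rng_seed = 5))
  c <- synthesize_lesion(phantom_spec(true_diameter_cm = 3, rng_seed = 6))
  expect_identical(a$image, b$image)
  expect_identical(a$seed_point, b$seed_point)
  expect_false(identical(a$image, c$image))
})

test_that("oversized lesions are rejected with a sizing error", {
  expect_error(phantom_spec(true_diameter_cm = 30, pixel_spacing_cm = 0.1,
                            image_size_px = 256),
               class = "lesionruler_sizing_error")
  # fits the invariant but not the rendered margin
  expect_error(synthesize_lesion(phantom_spec(true_diameter_cm = 25,
                                              pixel_spacing_cm = 0.1,
                                              image_size_px = 256, rng_seed = 1)),
               class = "lesionruler_sizing_error")
})

test_that("dataset sampling is reproducible, bounded, and covers all groups", {
  a <- sample_phantom_dataset(8, c(1.5, 5.0), c(0.06, 0.12), master_seed = 42)
  b <- sample_phantom_dataset(8, c(1.5, 5.0), c(0.06, 0.12), master_seed = 42)
  expect_identical(vapply(a, `[[`, 0, "true_diameter_cm"),
                   vapply(b, `[[`, 0, "true_diameter_cm"))
  expect_identical(a[[3]]$image, b[[3]]$image)
  d <- vapply(a, `[[`, 0, "true_diameter_cm")
  sp <- vapply(a, `[[`, 0, "spacing_cm")
  expect_true(all(d >= 1.5 & d <= 5.0))
  expect_true(all(sp >= 0.06 & sp <= 0.12))
  expect_setequal(unique(vapply(a[1:6], `[[`, "", "invasion_group")),
                  c("A", "B", "C", "D", "E", "F"))
  expect_error(sample_phantom_dataset(3, c(5, 1), c(0.06, 0.12)),
               class = "lesionruler_parameter_error")
})

test_that("phantom DICOM round-trips exactly through the reader", {
  case <- fixture_circle_case()
  path <- withr::local_tempfile(fileext = ".dcm")
  write_phantom_dicom(case, path)
  sl <- read_ct_slice(path)
  expect_identical(dim(sl$pixels), dim(case$image))
  expect_equal(unname(sl$pixels), unname(case$image + 0))
  expect_equal(sl$spacing_cm, c(0.1, 0.1))
  expect_equal(sl$window_center, -600)
  expect_equal(sl$window_width, 1500)
})

test_that("phantom DICOMs parse identically under an independent reader", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  case <- synthesize_lesion(phantom_spec(true_diameter_cm = 2.4,
                                         pixel_spacing_cm = 0.08, rng_seed = 33))
  path <- withr::local_tempfile(fileext = ".dcm")
  csvp <- withr::local_tempfile(fileext = ".csv")
  write_phantom_dicom(case, path)
  script <- sprintf(paste0(
    "import pydicom, numpy as np\n",
    "d = pydicom.dcmread(r'%s')\n",
    "arr = d.pixel_array.astype(float) * float(d.RescaleSlope) + float(d.RescaleIntercept)\n",
    "print(float(d.PixelSpacing[0]), float(d.PixelSpacing[1]), arr.sum(), arr[100, :].sum())\n"),
    path)
  out <- system2("python", "-", stdout = TRUE, input = script)
  skip_if(length(out) == 0, "pydicom unavailable")
  vals <- as.numeric(strsplit(out[length(out)], " ")[[1]])
  expect_equal(vals[1:2], rep(case$spacing_cm * 10, 2))
  expect_equal(vals[3], sum(case$image))
  expect_equal(vals[4], sum(case$image[101, ]))
})

test_that("annotation CSV writer and reader agree", {
  cases <- sample_phantom_dataset(4, master_seed = 9)
  csvp <- withr::local_tempfile(fileext = ".csv")
  df <- write_phantom_annotations(cases, sprintf("case%d.dcm", 1:4), csvp)
  back <- read_annotation_csv(csvp)
  expect_equal(back$true_diameter_cm, df$true_diameter_cm)
  expect_equal(back$seed_row, df$seed_row)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(case_id = "x"), bad, row.names = FALSE)
  expect_error(read_annotation_csv(bad), class = "lesionruler_format_error")
})
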