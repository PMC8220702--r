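# Synthetic lesion phantoms with exact ground-truth longest diameters.
# Ground truth is defined on the noiseless continuous shape (normalised so
# its longest chord equals the requested diameter exactly); the rendered
# mask agrees with a brute-force boundary-chord oracle to within one pixel
# diagonal.  Intensities are on a Hounsfield-like integer scale.

PHANTOM_SHAPES <- c("smooth_ellipse", "spiculated", "adjacent_pair", "central_density")
INVASION_GROUPS <- c("A", "B", "C", "D", "E", "F")

PHANTOM_BG_HU <- -750     # parenchyma-like background level
PHANTOM_LESION_HU <- 20   # soft-tissue-like lesion level
PHANTOM_CORE_HU <- 150    # bright central density (central_density family)
PHANTOM_TEXTURE_SD <- 40  # correlated background texture amplitude (HU)

#' Specify a synthetic lesion phantom
#'
#' @param shape_family One of `"smooth_ellipse"`, `"spiculated"`,
#'   `"adjacent_pair"`, `"central_density"`.  The non-elliptical families
#'   emulate the morphologies that make real measurements ambiguous:
#'   spiculations, two lesions sharing a field of view, and a bright central
#'   density.
#' @param true_diameter_cm Longest diameter of the lesion, cm (> 0).
#' @param aspect_ratio Minor/major axis ratio in `[0.4, 1]`.
#' @param rotation_deg Major-axis direction, degrees in `[0, 180)` (0 = along
#'   image columns).
#' @param spiculation_count,spiculation_length_frac Number of boundary spikes
#'   and their length as a fraction of the local radius (spiculated family).
#' @param noise_sd White-noise standard deviation added to the render, HU.
#' @param pixel_spacing_cm Pixel spacing, cm per pixel (> 0).
#' @param image_size_px Square image side, pixels (>= 256).
#' @param rng_seed Integer seed; synthesis is deterministic given it.
#' @return A validated `phantom_spec` object.
#' @export
phantom_spec <- function(shape_family = "smooth_ellipse", true_diameter_cm = 3,
                         aspect_ratio = 0.8, rotation_deg = 0,
                         spiculation_count = 8, spiculation_length_frac = 0.2,
                         noise_sd = 20, pixel_spacing_cm = 0.1,
                         image_size_px = 256, rng_seed = 1) {
  shape_family <- match.arg(shape_family, PHANTOM_SHAPES)
  if (!is.finite(true_diameter_cm) || true_diameter_cm <= 0)
    stop_lesionruler("true_diameter_cm must be > 0", "lesionruler_parameter_error")
  if (aspect_ratio < 0.4 || aspect_ratio > 1)
    stop_lesionruler("aspect_ratio must be in [0.4, 1]", "lesionruler_parameter_error")
  if (rotation_deg < 0 || rotation_deg >= 180)
    stop_lesionruler("rotation_deg must be in [0, 180)", "lesionruler_parameter_error")
  if (spiculation_count < 0 || spiculation_length_frac < 0 || spiculation_length_frac > 0.5)
    stop_lesionruler("invalid spiculation parameters", "lesionruler_parameter_error")
  if (noise_sd < 0 || pixel_spacing_cm <= 0)
    stop_lesionruler("noise_sd must be >= 0 and pixel_spacing_cm > 0",
                     "lesionruler_parameter_error")
  if (image_size_px < 256)
    stop_lesionruler("image_size_px must be >= 256", "lesionruler_parameter_error")
  if (true_diameter_cm / pixel_spacing_cm > image_size_px)
    stop_lesionruler("lesion would exceed image bounds", "lesionruler_sizing_error")
  if (PHANTOM_LESION_HU < PHANTOM_BG_HU + 5 * noise_sd)
    stop_lesionruler("noise_sd too large for the required figure/ground contrast",
                     "lesionruler_parameter_error")
  structure(list(shape_family = shape_family, true_diameter_cm = true_diameter_cm,
                 aspect_ratio = aspect_ratio, rotation_deg = rotation_deg,
                 spiculation_count = spiculation_count,
                 spiculation_length_frac = spiculation_length_frac,
                 noise_sd = noise_sd, pixel_spacing_cm = pixel_spacing_cm,
                 image_size_px = as.integer(image_size_px), rng_seed = rng_seed),
            class = "phantom_spec")
}

# separable blur with edge replication; k is a normalised odd-length kernel
blur_sep <- function(m, k) {
  h <- (length(k) - 1) / 2
  pad_filter <- function(mm) {
    padded <- rbind(mm[rep(1, h), , drop = FALSE], mm,
                    mm[rep(nrow(mm), h), , drop = FALSE])
    out <- stats::filter(padded, k, sides = 2)
    matrix(out[(h + 1):(h + nrow(mm)), ], nrow = nrow(mm))
  }
  t(pad_filter(t(pad_filter(m))))
}

gauss_kernel <- function(sigma) {
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  k / sum(k)
}

# Unscaled shape geometry in the shape frame (major axis along +x).
# Returns list(inside = function(sx, sy), chord_len, endpoints 2x2 (x, y),
# max_radius) for a shape whose longest chord is chord_len.
phantom_geometry <- function(spec) {
  a <- 1
  b <- spec$aspect_ratio
  switch(spec$shape_family,
    smooth_ellipse = ,
    central_density = list(
      inside = function(sx, sy) (sx / a)^2 + (sy / b)^2 <= 1,
      chord_len = 2 * a,
      endpoints = rbind(c(-a, 0), c(a, 0)),
      max_radius = a),
    spiculated = {
      K <- max(1L, as.integer(spec$spiculation_count))
      L <- spec$spiculation_length_frac
      phase <- stats::runif(1, 0, 2 * pi / K)
      w <- pi / (3 * K)  # spike half-width (radians)
      rfun <- function(theta) {
        r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
        d <- (theta - phase) %% (2 * pi / K)
        d <- pmin(d, 2 * pi / K - d)      # distance to nearest spike centre
        bump <- ifelse(d < w, cos(pi * d / (2 * w))^2, 0)
        r_ell * (1 + L * bump)
      }
      theta <- seq(0, 2 * pi, length.out = 2881)[-2881]
      bx <- rfun(theta) * cos(theta)
      by <- rfun(theta) * sin(theta)
      hull <- grDevices::chull(bx, by)
      hx <- bx[hull]; hy <- by[hull]
      dd <- outer(hx, hx, "-")^2 + outer(hy, hy, "-")^2
      ij <- arrayInd(which.max(dd), dim(dd))
      list(
        inside = function(sx, sy) {
          r <- sqrt(sx^2 + sy^2)
          r <= rfun(atan2(sy, sx))
        },
        chord_len = sqrt(max(dd)),
        endpoints = rbind(c(hx[ij[1]], hy[ij[1]]), c(hx[ij[2]], hy[ij[2]])),
        max_radius = max(sqrt(bx^2 + by^2)))
    },
    adjacent_pair = {
      # two overlapping lobes spanning a unit-length union; each lobe
      # diameter strictly below the union's longest chord
      r1 <- 0.33; r2 <- 0.27
      x1 <- -0.5 + r1; x2 <- 0.5 - r2
      list(
        inside = function(sx, sy)
          ((sx - x1)^2 + sy^2 <= r1^2) | ((sx - x2)^2 + sy^2 <= r2^2),
        chord_len = 1,
        endpoints = rbind(c(-0.5, 0), c(0.5, 0)),
        max_radius = 0.5,
        lobe_centers = rbind(c(x1, 0), c(x2, 0)),
        lobe_radii = c(r1, r2))
    })
}

#' Synthesize a lesion phantom
#'
#' Renders the specified lesion as a bright region on textured,
#' parenchyma-like background and returns it together with the exact
#' ground-truth longest diameter, its endpoints, and an interior seed point.
#' The continuous shape is scaled so that its longest chord equals
#' `true_diameter_cm` exactly; the returned binary `mask` is its
#' rasterization (pixel centers inside the shape), on which a brute-force
#' boundary-chord oracle agrees to within one pixel diagonal.
#'
#' @param spec A [phantom_spec()].
#' @param case_id Identifier attached to the case.
#' @param invasion_group Arbitrary group label `"A"`–`"F"` used by the
#'   group-comparison statistics (phantoms have no anatomy; the label simply
#'   exercises the stratified analysis).
#' @return A `phantom_case`: `image` (integer HU-like matrix), `mask`,
#'   `spacing_cm`, `seed_point` (0-based row/col), `true_diameter_cm`,
#'   `true_endpoints` (2x2, 0-based row/col), `shape_family`,
#'   `invasion_group`, window settings and `case_id`.
#' @examples
#' case <- synthesize_lesion(phantom_spec(true_diameter_cm = 3.2,
#'                                        aspect_ratio = 1, rng_seed = 7))
#' case$true_diameter_cm
#' @export
synthesize_lesion <- function(spec, case_id = "phantom", invasion_group = "A") {
  stopifnot(inherits(spec, "phantom_spec"))
  invasion_group <- match.arg(invasion_group, INVASION_GROUPS)
  with_seed(spec$rng_seed, {
    N <- spec$image_size_px
    d_px <- spec$true_diameter_cm / spec$pixel_spacing_cm
    geo <- phantom_geometry(spec)
    s <- d_px / geo$chord_len

    center <- (N - 1) / 2 + stats::runif(2, -N / 16, N / 16)
    if (any(center - s * geo$max_radius < 2) || any(center + s * geo$max_radius > N - 3))
      stop_lesionruler("lesion would exceed image bounds", "lesionruler_sizing_error")

    rho <- spec$rotation_deg * pi / 180
    co <- cos(rho); si <- sin(rho)
    dr <- matrix(seq_len(N) - 1 - center[1], N, N)
    dc <- matrix(seq_len(N) - 1 - center[2], N, N, byrow = TRUE)
    sx <- (dc * co + dr * si) / s
    sy <- (-dc * si + dr * co) / s
    mask <- geo$inside(sx, sy)
    dim(mask) <- c(N, N)

    shape_to_image <- function(p)  # (x, y) shape frame -> (row, col) image
      c(center[1] + s * (p[1] * si + p[2] * co),
        center[2] + s * (p[1] * co - p[2] * si))
    endpoints <- t(apply(geo$endpoints, 1, shape_to_image))

    tex <- matrix(stats::rnorm(N * N), N, N)
    tex <- blur_sep(tex, gauss_kernel(3))
    tex <- tex / stats::sd(tex) * PHANTOM_TEXTURE_SD
    img <- matrix(PHANTOM_BG_HU, N, N) + tex
    img[mask] <- PHANTOM_LESION_HU
    if (spec$shape_family == "central_density") {
      core <- (sx / 0.3)^2 + (sy / (0.3 * spec$aspect_ratio))^2 <= 1
      img[core] <- PHANTOM_CORE_HU
    }
    img <- blur_sep(img, gauss_kernel(0.6))           # soft lesion edge
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(N * N, 0, spec$noise_sd), N, N)
    img <- matrix(as.integer(pmax(round(img), -1024)), N, N)

    # interior seed: mask pixel (with all 4-neighbours in the mask) nearest
    # to the primary lobe / shape centre
    target <- if (spec$shape_family == "adjacent_pair")
      shape_to_image(geo$lobe_centers[1, ]) else center
    interior <- mask
    interior[2:(N - 1), 2:(N - 1)] <-
      mask[2:(N - 1), 2:(N - 1)] & mask[1:(N - 2), 2:(N - 1)] &
      mask[3:N, 2:(N - 1)] & mask[2:(N - 1), 1:(N - 2)] & mask[2:(N - 1), 3:N]
    idx <- which(interior, arr.ind = TRUE) - 1L   # 0-based
    if (nrow(idx) == 0) idx <- which(mask, arr.ind = TRUE) - 1L
    nearest <- which.min((idx[, 1] - target[1])^2 + (idx[, 2] - target[2])^2)
    seed_point <- as.integer(idx[nearest, ])

    structure(list(image = img, mask = mask, spacing_cm = spec$pixel_spacing_cm,
                   seed_point = seed_point,
                   true_diameter_cm = spec$true_diameter_cm,
                   true_endpoints = unname(endpoints),
                   shape_family = spec$shape_family,
                   invasion_group = invasion_group,
                   window_center = -600, window_width = 1500,
                   case_id = case_id, spec = spec),
              class = "phantom_case")
  })
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf("<phantom_case %s: %s, d = %.3f cm, spacing %.3f cm/px, %d px, group %s>\n",
              x$case_id, x$shape_family, x$true_diameter_cm, x$spacing_cm,
              nrow(x$image), x$invasion_group))
  invisible(x)
}

#' Convert a phantom case to a CT slice
#'
#' @param case A `phantom_case`.
#' @return A [ct_slice()] sharing the phantom's pixels and spacing.
#' @export
as_ct_slice <- function(case) {
  stopifnot(inherits(case, "phantom_case"))
  ct_slice(case$image, spacing_cm = case$spacing_cm,
           window_center = case$window_center, window_width = case$window_width,
           source_id = case$case_id)
}

#' Sample a reproducible phantom dataset
#'
#' Draws `n` phantom cases with diameters and pixel spacings approximately
#' uniform over the given ranges; shape families and invasion-group labels
#' are cycled so that every group is populated once `n >= 6`.  Defaults span
#' the measurement range (1.37–5.44 cm) and in-plane resolutions
#' (0.051–0.137 cm/px) typical of clinical lung CT.
#'
#' @param n Number of cases (>= 1).
#' @param diameter_range_cm,spacing_range_cm `(lo, hi)` ranges, `0 < lo < hi`.
#' @param master_seed Integer; the whole dataset is reproducible given it.
#' @param image_size_px Side of each square phantom image.
#' @param noise_sd White-noise SD passed to each spec.
#' @return List of `phantom_case` objects.
#' @export
sample_phantom_dataset <- function(n, diameter_range_cm = c(1.37, 5.44),
                                   spacing_range_cm = c(0.051, 0.137),
                                   master_seed = 1, image_size_px = 256,
                                   noise_sd = 20) {
  if (n < 1)
    stop_lesionruler("n must be >= 1", "lesionruler_parameter_error")
  ok_range <- function(r) length(r) == 2 && all(is.finite(r)) && r[1] > 0 && r[1] < r[2]
  if (!ok_range(diameter_range_cm) || !ok_range(spacing_range_cm))
    stop_lesionruler("ranges must satisfy 0 < lo < hi", "lesionruler_parameter_error")
  with_seed(master_seed, {
    d <- stats::runif(n, diameter_range_cm[1], diameter_range_cm[2])
    sp <- stats::runif(n, spacing_range_cm[1], spacing_range_cm[2])
    aspect <- stats::runif(n, 0.55, 1)
    rot <- stats::runif(n, 0, 180)
    spic_n <- sample(6:12, n, replace = TRUE)
    spic_l <- stats::runif(n, 0.1, 0.3)
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      spec <- phantom_spec(
        shape_family = PHANTOM_SHAPES[(i - 1) %% length(PHANTOM_SHAPES) + 1],
        true_diameter_cm = d[i], aspect_ratio = aspect[i], rotation_deg = rot[i],
        spiculation_count = spic_n[i], spiculation_length_frac = spic_l[i],
        noise_sd = noise_sd, pixel_spacing_cm = sp[i],
        image_size_px = image_size_px, rng_seed = seeds[i])
      synthesize_lesion(spec, case_id = sprintf("case_%04d", i),
                        invasion_group = INVASION_GROUPS[(i - 1) %% 6 + 1])
    })
  })
}

#' Write a phantom case as a DICOM file
#'
#' Emits a single-frame, secondary-capture-style DICOM whose PixelSpacing
#' tag (mm) equals `spacing_cm * 10`; reading it back with [read_ct_slice()]
#' recovers pixel values and spacing exactly.
#'
#' @param case A `phantom_case`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phantom_dicom <- function(case, path) {
  stopifnot(inherits(case, "phantom_case"))
  dcm_write_slice(case$image, rep(case$spacing_cm, 2), case$window_center,
                  case$window_width, path, source_id = case$case_id)
}

#' Write the companion annotation table for a set of phantoms
#'
#' @param cases List of `phantom_case` objects.
#' @param paths Character vector of the DICOM paths they were written to.
#' @param file CSV output path.
#' @return The annotation data frame, invisibly.
#' @export
write_phantom_annotations <- function(cases, paths, file) {
  df <- data.frame(
    case_id = vapply(cases, `[[`, "", "case_id"),
    path = paths,
    seed_row = vapply(cases, function(x) x$seed_point[1], 0),
    seed_col = vapply(cases, function(x) x$seed_point[2], 0),
    true_diameter_cm = vapply(cases, `[[`, 0, "true_diameter_cm"),
    spacing_cm = vapply(cases, `[[`, 0, "spacing_cm"),
    shape_family = vapply(cases, `[[`, "", "shape_family"),
    invasion_group = vapply(cases, `[[`, "", "invasion_group"))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(df)
}

#' Read an annotation table
#'
#' @param file CSV path with columns `case_id, path, seed_row, seed_col,
#'   true_diameter_cm, spacing_cm` (and optionally `shape_family`,
#'   `invasion_group`).
#' @return A data frame.
#' @export
read_annotation_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("case_id", "seed_row", "seed_col", "true_diameter_cm", "spacing_cm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_lesionruler(paste("annotation CSV lacks columns:",
                           paste(miss, collapse = ", ")),
                     "lesionruler_format_error")
  df
}
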