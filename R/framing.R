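# Geometric canonicalization: cm <-> pixel conversion, bicubic
# magnification, 128x128 framing, and label-preserving augmentation.
# The canonical move: magnify by 32/M_px so the lesion spans exactly 32
# pixels, then crop a 128x128 frame about the measurement center.

FRAME_SIZE <- 128L
TARGET_PX <- 32

#' Convert a physical measurement to pixels
#'
#' `M_px = measurement_cm / spacing_cm`, the lesion's diameter expressed in
#' pixels of the source image.
#'
#' @param measurement_cm Measurement in cm (> 0).
#' @param spacing_cm Pixel spacing in cm per pixel (> 0).
#' @return The measurement in pixels.
#' @examples
#' cm_to_pixels(3.2, 0.1)  # 32
#' @export
cm_to_pixels <- function(measurement_cm, spacing_cm) {
  if (any(measurement_cm <= 0) || any(spacing_cm <= 0))
    stop_lesionruler("measurement and spacing must be > 0", "lesionruler_parameter_error")
  measurement_cm / spacing_cm
}

#' Canonical magnification for a lesion of M_px pixels
#'
#' The factor `32 / M_px` that rescales an image so the target lesion spans
#' exactly 32 pixels.
#'
#' @param M_px Lesion size in pixels (> 0).
#' @return The magnification factor.
#' @export
canonical_magnification <- function(M_px) {
  if (any(M_px <= 0))
    stop_lesionruler("M_px must be > 0", "lesionruler_parameter_error")
  TARGET_PX / M_px
}

#' Bicubic resampling
#'
#' Rescales an image by a magnification factor using Catmull-Rom bicubic
#' interpolation (pixel-center convention; output dimensions are
#' `round(input * magnification)`, distances scale by the factor).
#'
#' @param image Numeric matrix.
#' @param magnification Positive scale factor; length-1 (isotropic) or
#'   length-2 `(row, col)`.
#' @return The resampled matrix.
#' @export
resample_bicubic <- function(image, magnification) {
  if (length(magnification) == 1) magnification <- rep(magnification, 2)
  if (any(!is.finite(magnification)) || any(magnification <= 0))
    stop_lesionruler("magnification must be > 0", "lesionruler_parameter_error")
  if (round(nrow(image) * magnification[1]) < 1 ||
      round(ncol(image) * magnification[2]) < 1)
    stop_lesionruler("resampled image would be smaller than 1x1",
                     "lesionruler_parameter_error")
  cpp_resample(image, magnification[1], magnification[2])
}

#' Crop a square frame about a center point
#'
#' Extracts a `size x size` window whose center index `(size/2, size/2)`
#' (0-based) coincides with `center`; regions falling outside the image are
#' padded with `fill`.
#'
#' @param image Numeric matrix.
#' @param center 0-based `(row, col)` integer pair, inside the image.
#' @param size Frame side (default 128).
#' @param fill Padding value (default 0, air-like after windowing).
#' @return A `size x size` matrix.
#' @export
crop_frame <- function(image, center, size = FRAME_SIZE, fill = 0) {
  center <- as.integer(round(center))
  if (center[1] < 0 || center[1] >= nrow(image) ||
      center[2] < 0 || center[2] >= ncol(image))
    stop_lesionruler("center must lie inside the image", "lesionruler_parameter_error")
  half <- size %/% 2
  out <- matrix(fill, size, size)
  r0 <- center[1] - half; c0 <- center[2] - half    # 0-based frame origin
  rows <- max(0, r0):min(nrow(image) - 1, r0 + size - 1)
  cols <- max(0, c0):min(ncol(image) - 1, c0 + size - 1)
  out[rows - r0 + 1, cols - c0 + 1] <- image[rows + 1, cols + 1]
  out
}

#' Construct a frame object
#'
#' A 128x128 intensity patch at a known magnification, optionally carrying
#' the larger/smaller-than-32-pixels label used for classifier training.
#'
#' @param patch `size x size` numeric matrix in `[0, 1]`.
#' @param magnification The magnification at which the patch was sampled.
#' @param source_spacing_cm Pixel spacing of the source image (cm/px).
#' @param frame_center_source Frame center in resampled coordinates.
#' @param label `"SMALLER"`, `"LARGER"`, or `NULL`.
#' @param apparent_size_px The lesion's apparent size in the patch, pixels.
#' @param zoom,shift Augmentation bookkeeping.
#' @return A `lesion_frame` object.
#' @export
lesion_frame <- function(patch, magnification, source_spacing_cm = NA_real_,
                         frame_center_source = c(NA_real_, NA_real_),
                         label = NULL, apparent_size_px = NULL,
                         zoom = NA_real_, shift = c(0L, 0L)) {
  if (!is.matrix(patch) || nrow(patch) != FRAME_SIZE || ncol(patch) != FRAME_SIZE)
    stop_lesionruler("patch must be exactly 128x128", "lesionruler_parameter_error")
  if (!is.null(label)) {
    label <- match.arg(label, c("SMALLER", "LARGER"))
    if (!is.null(apparent_size_px) &&
        ((label == "LARGER") != (apparent_size_px >= TARGET_PX)))
      stop_lesionruler("label inconsistent with apparent_size_px",
                       "lesionruler_parameter_error")
  }
  structure(list(patch = patch, magnification = magnification,
                 source_spacing_cm = source_spacing_cm,
                 frame_center_source = frame_center_source, label = label,
                 apparent_size_px = apparent_size_px, zoom = zoom, shift = shift),
            class = "lesion_frame")
}

#' Extract a classification frame from a windowed image
#'
#' Resamples the image by `magnification`, maps the seed point to resampled
#' coordinates (round half away from zero), applies an optional shift, and
#' crops the 128x128 frame.  Only the needed pixels are computed.
#'
#' @param image Windowed (`[0, 1]`) numeric matrix.
#' @param seed 0-based `(row, col)` point inside the image.
#' @param magnification Positive scale factor.
#' @param source_spacing_cm Carried into the frame metadata.
#' @param fill Padding value.
#' @param shift Integer `(row, col)` shift of the frame center, in resampled
#'   pixels.
#' @return A `lesion_frame`.
#' @export
extract_frame <- function(image, seed, magnification, source_spacing_cm = NA_real_,
                          fill = 0, shift = c(0L, 0L)) {
  if (seed[1] < 0 || seed[1] >= nrow(image) || seed[2] < 0 || seed[2] >= ncol(image))
    stop_lesionruler("seed must lie inside the image", "lesionruler_parameter_error")
  mapped <- round_half_away(magnification * (seed + 0.5) - 0.5)
  center <- as.integer(mapped + shift)
  patch <- cpp_resample_crop(image, magnification, center[1], center[2],
                             FRAME_SIZE, fill)
  lesion_frame(patch, magnification = magnification,
               source_spacing_cm = source_spacing_cm,
               frame_center_source = center, shift = as.integer(shift))
}

#' Augmentation policy for training-frame preparation
#'
#' @param zoom_factors Positive zoom factors applied on top of the canonical
#'   magnification; the default geometric grid over `[0.5, 2]` spans apparent
#'   sizes 16–64 px, symmetric (in log) about the 32 px decision boundary.
#' @param max_shift_px Maximum per-axis frame-center shift, resampled pixels.
#'   The default 16 matches the displacement an arbitrary interior seed point
#'   can induce near the decision boundary, where the lesion spans 32 px and
#'   no interior point is farther than one radius from the center.
#' @param per_image_count Frames generated per source image (zoom factors are
#'   cycled).
#' @param balance Equalize SMALLER/LARGER counts by seeded subsampling of the
#'   majority class.
#' @param exclusion_band_px Frames with `|apparent_size - 32|` below this are
#'   dropped (their label is undefined at the boundary).
#' @return An `augmentation_policy` object.
#' @export
augmentation_policy <- function(zoom_factors = exp(seq(log(0.5), log(2), length.out = 18)),
                                max_shift_px = 16L, per_image_count = 54L,
                                balance = TRUE, exclusion_band_px = 0.5) {
  if (any(zoom_factors <= 0) || max_shift_px < 0 || per_image_count < 1 ||
      exclusion_band_px < 0)
    stop_lesionruler("invalid augmentation policy", "lesionruler_parameter_error")
  if (max_shift_px >= FRAME_SIZE / 2)
    stop_lesionruler("max_shift_px must keep the lesion center inside the frame",
                     "lesionruler_parameter_error")
  structure(list(zoom_factors = zoom_factors, max_shift_px = as.integer(max_shift_px),
                 per_image_count = as.integer(per_image_count), balance = balance,
                 exclusion_band_px = exclusion_band_px),
            class = "augmentation_policy")
}

#' Prepare labeled training frames from an annotated image
#'
#' Each frame is built by resampling at `zoom * 32 / M_px` (so the lesion's
#' apparent size is `zoom * 32` px), shifting the frame center by a random
#' integer offset, and cropping 128x128 about the measurement center.  The
#' label is LARGER iff the apparent size exceeds 32 px (an exact 32 with a
#' zero exclusion band is labeled LARGER by convention); frames inside the
#' exclusion band are dropped.  With `balance = TRUE` the majority class is
#' subsampled (seeded) to yield exactly equal class counts.
#'
#' @param x A `phantom_case` (measurement center and `M_px` are derived from
#'   its ground truth), a `ct_slice`, or a windowed numeric matrix.
#' @param center 0-based measurement center (required unless `x` is a
#'   `phantom_case`).
#' @param M_px Lesion size in source pixels (required unless `x` is a
#'   `phantom_case`).
#' @param policy An [augmentation_policy()].
#' @param rng_seed Integer seed controlling shifts and balancing.
#' @return List of labeled `lesion_frame` objects (possibly empty, with a
#'   warning, if every frame fell in the exclusion band).
#' @export
prepare_training_frames <- function(x, center = NULL, M_px = NULL,
                                    policy = augmentation_policy(), rng_seed = 1) {
  if (inherits(x, "phantom_case")) {
    if (is.null(center)) center <- colMeans(x$true_endpoints)
    if (is.null(M_px)) M_px <- cm_to_pixels(x$true_diameter_cm, x$spacing_cm)
    spacing <- x$spacing_cm
    image <- apply_window(as_ct_slice(x))
  } else if (inherits(x, "ct_slice")) {
    spacing <- x$spacing_cm[1]
    image <- apply_window(x)
  } else {
    spacing <- NA_real_
    image <- x
  }
  if (is.null(center) || is.null(M_px) || M_px <= 0)
    stop_lesionruler("center and positive M_px are required",
                     "lesionruler_parameter_error")

  with_seed(rng_seed, {
    zooms <- rep_len(policy$zoom_factors, policy$per_image_count)
    shift_pool <- seq(-policy$max_shift_px, policy$max_shift_px)
    frames <- list()
    for (i in seq_along(zooms)) {
      z <- zooms[i]
      apparent <- z * TARGET_PX
      sh <- c(sample(shift_pool, 1), sample(shift_pool, 1))
      if (abs(apparent - TARGET_PX) < policy$exclusion_band_px) next
      f <- extract_frame(image, center, z * canonical_magnification(M_px),
                         source_spacing_cm = spacing, shift = sh)
      f$label <- if (apparent >= TARGET_PX) "LARGER" else "SMALLER"
      f$apparent_size_px <- apparent
      f$zoom <- z
      frames[[length(frames) + 1]] <- f
    }
    if (length(frames) == 0) {
      warning(warningCondition("all frames fell inside the exclusion band",
                               class = "lesionruler_empty_frames"))
      return(list())
    }
    if (policy$balance) frames <- balance_frames(frames)
    frames
  })
}

#' Balance a frame set to equal class counts
#'
#' Subsamples the majority class (using the current RNG stream) so that
#' SMALLER and LARGER counts are exactly equal.
#'
#' @param frames List of labeled `lesion_frame` objects.
#' @return A list with equal class counts.
#' @export
balance_frames <- function(frames) {
  labels <- vapply(frames, `[[`, "", "label")
  n_small <- sum(labels == "SMALLER")
  n_large <- sum(labels == "LARGER")
  k <- min(n_small, n_large)
  keep_small <- which(labels == "SMALLER")
  keep_large <- which(labels == "LARGER")
  if (n_small > k) keep_small <- sort(sample(keep_small, k))
  if (n_large > k) keep_large <- sort(sample(keep_large, k))
  frames[sort(c(keep_small, keep_large))]
}

#' Write a frame set as images plus a manifest
#'
#' @param frames List of labeled `lesion_frame` objects.
#' @param dir Output directory (created if needed); frames are written as
#'   `frame_%05d.png` when the png package is available, otherwise as
#'   plain-text CSV grids.
#' @return The manifest data frame, invisibly (also written to
#'   `manifest.csv` in `dir`).
#' @export
write_frame_set <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  has_png <- requireNamespace("png", quietly = TRUE)
  ids <- sprintf("frame_%05d", seq_along(frames))
  files <- character(length(frames))
  for (i in seq_along(frames)) {
    if (has_png) {
      files[i] <- file.path(dir, paste0(ids[i], ".png"))
      png::writePNG(frames[[i]]$patch, files[i])
    } else {
      files[i] <- file.path(dir, paste0(ids[i], ".csv"))
      utils::write.table(frames[[i]]$patch, files[i], sep = ",",
                         row.names = FALSE, col.names = FALSE)
    }
  }
  manifest <- data.frame(
    frame_id = ids, path = files,
    label = vapply(frames, function(f) f$label %||% NA_character_, ""),
    apparent_size_px = vapply(frames, function(f) f$apparent_size_px %||% NA_real_, 0),
    zoom = vapply(frames, `[[`, 0, "zoom"),
    shift_row = vapply(frames, function(f) f$shift[1], 0L),
    shift_col = vapply(frames, function(f) f$shift[2], 0L))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
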