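#' Construct a CT slice object
#'
#' Container for a single cross-sectional CT slice: a calibrated pixel grid
#' (Hounsfield-like units), the physical pixel spacing, and display window
#' settings.  All coordinates in the package are 0-based `(row, col)` pairs.
#'
#' @param pixels Numeric matrix of calibrated intensities.
#' @param spacing_cm Pixel spacing in cm per pixel; length-1 (isotropic) or
#'   length-2 `(row, col)`.
#' @param window_center,window_width Display window (defaults: lung window,
#'   center -600, width 1500).
#' @param source_id Identifier carried through to results.
#' @return An object of class `ct_slice`.
#' @export
ct_slice <- function(pixels, spacing_cm, window_center = -600,
                     window_width = 1500, source_id = "slice") {
  if (!is.matrix(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1)
    stop_lesionruler("pixels must be a non-empty matrix", "lesionruler_parameter_error")
  spacing_cm <- as.numeric(spacing_cm)
  if (length(spacing_cm) == 1) spacing_cm <- rep(spacing_cm, 2)
  if (length(spacing_cm) != 2 || any(!is.finite(spacing_cm)) || any(spacing_cm <= 0))
    stop_lesionruler("spacing_cm must be positive", "lesionruler_parameter_error")
  if (!is.finite(window_width) || window_width <= 0)
    stop_lesionruler("window_width must be > 0", "lesionruler_parameter_error")
  structure(list(pixels = pixels, spacing_cm = spacing_cm,
                 window_center = window_center, window_width = window_width,
                 source_id = source_id),
            class = "ct_slice")
}

#' @export
print.ct_slice <- function(x, ...) {
  cat(sprintf("<ct_slice %s: %d x %d px, spacing %.4f x %.4f cm, window C%g/W%g>\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels),
              x$spacing_cm[1], x$spacing_cm[2], x$window_center, x$window_width))
  invisible(x)
}

#' Apply display windowing
#'
#' Maps calibrated intensities to `[0, 1]` with the linear window transform
#' `clip((p - (center - width/2)) / width, 0, 1)`.  This is the normalization
#' fed to the size classifier.
#'
#' @param x A `ct_slice` or a numeric matrix/vector.
#' @param center,width Window center and width; taken from the slice when `x`
#'   is a `ct_slice`.
#' @return Numeric array of the same shape with values in `[0, 1]`.
#' @examples
#' apply_window(-600, center = -600, width = 1500)  # 0.5 at the center
#' @export
apply_window <- function(x, center = NULL, width = NULL) {
  if (inherits(x, "ct_slice")) {
    if (is.null(center)) center <- x$window_center
    if (is.null(width)) width <- x$window_width
    x <- x$pixels
  }
  if (is.null(center) || is.null(width))
    stop_lesionruler("center and width required for raw input", "lesionruler_parameter_error")
  if (width <= 0)
    stop_lesionruler("window width must be > 0", "lesionruler_parameter_error")
  pmin(pmax((x - (center - width / 2)) / width, 0), 1)
}

#' Read a CT slice from a DICOM file
#'
#' Parses a single-frame, uncompressed, explicit-VR little-endian DICOM file.
#' Rescale slope/intercept are applied to the stored pixel values and the
#' PixelSpacing tag (mm) is converted to cm.  Missing window tags fall back
#' to the supplied defaults; a missing PixelSpacing tag is an error because
#' physical measurement is impossible without it.
#'
#' @param path Path to the DICOM file.
#' @param default_window Numeric `c(center, width)` used when the file has no
#'   window tags (default: lung window -600/1500).
#' @return A [ct_slice()].
#' @export
read_ct_slice <- function(path, default_window = c(-600, 1500)) {
  els <- dcm_parse(path)
  rows <- dcm_us(els, "00280010")
  cols <- dcm_us(els, "00280011")
  if (is.null(rows) || is.null(cols))
    stop_lesionruler("DICOM lacks Rows/Columns", "lesionruler_format_error")
  bits <- dcm_us(els, "00280100")
  if (is.null(bits) || bits != 16L)
    stop_lesionruler("only 16-bit pixel data supported", "lesionruler_format_error")
  pixrep <- dcm_us(els, "00280103")
  if (is.null(pixrep)) pixrep <- 0L
  pd <- els[["7FE00010"]]
  if (is.null(pd) || length(pd$value) < 2L * rows * cols)
    stop_lesionruler("DICOM pixel data absent or truncated", "lesionruler_format_error")
  spacing <- dcm_ds(els, "00280030")
  if (is.null(spacing))
    stop_lesionruler("DICOM lacks PixelSpacing; physical measurement impossible",
                     "lesionruler_metadata_error")
  if (length(spacing) == 1) spacing <- rep(spacing, 2)
  slope <- dcm_ds(els, "00281053"); if (is.null(slope)) slope <- 1
  intercept <- dcm_ds(els, "00281052"); if (is.null(intercept)) intercept <- 0
  wc <- dcm_ds(els, "00281050"); if (is.null(wc)) wc <- default_window[1]
  ww <- dcm_ds(els, "00281051"); if (is.null(ww)) ww <- default_window[2]
  sop <- dcm_str(els, "00080018")
  if (is.null(sop)) sop <- basename(path)

  vals <- readBin(pd$value, "integer", n = rows * cols, size = 2,
                  signed = (pixrep == 1L), endian = "little")
  if (pixrep == 0L) vals[vals < 0] <- vals[vals < 0] + 65536L
  pixels <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE) * slope[1] + intercept[1]
  ct_slice(pixels, spacing_cm = spacing / 10, window_center = wc[1],
           window_width = ww[1], source_id = sop)
}
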