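# Minimal single-frame DICOM reader/writer (explicit VR, little endian).
# Covers exactly the secondary-capture-style files the phantom module emits
# and the tags the measurement pipeline needs; anything else is rejected
# with a format error rather than guessed at.

UID_TRANSFER_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"

dcm_u16 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
dcm_u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

dcm_str_raw <- function(s, pad = charToRaw(" ")) {
  r <- charToRaw(s)
  if (length(r) %% 2 == 1) r <- c(r, pad)
  r
}

dcm_element <- function(group, elem, vr, value) {
  long <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  c(dcm_u16(group), dcm_u16(elem), charToRaw(vr),
    if (long) c(as.raw(c(0, 0)), dcm_u32(length(value))) else dcm_u16(length(value)),
    value)
}

dcm_new_uid <- function() {
  # 2.25-rooted numeric UID from the R RNG; uniqueness is best-effort
  paste0("2.25.", paste(sample(0:9, 1), collapse = ""),
         paste(sample(0:9, 28, replace = TRUE), collapse = ""))
}

# Write a single-frame unsigned-16-bit DICOM.  `pixels` are calibrated
# (HU-like) integers; stored value = pixel - intercept with intercept -1024.
dcm_write_slice <- function(pixels, spacing_cm, window_center, window_width,
                            path, source_id = "PHANTOM") {
  if (any(pixels != round(pixels)))
    stop_lesionruler("pixel values must be integers for lossless storage",
                     "lesionruler_parameter_error")
  intercept <- -1024
  stored <- as.integer(round(pixels)) - intercept
  if (any(stored < 0) || any(stored > 65535))
    stop_lesionruler("pixel values outside storable range [-1024, 64511]",
                     "lesionruler_parameter_error")
  if (length(spacing_cm) == 1) spacing_cm <- rep(spacing_cm, 2)
  spacing_mm <- formatC(spacing_cm * 10, format = "fg", digits = 10)

  sop_uid <- dcm_new_uid()
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_element(0x0002, 0x0002, "UI", dcm_str_raw(UID_SECONDARY_CAPTURE, as.raw(0))),
    dcm_element(0x0002, 0x0003, "UI", dcm_str_raw(sop_uid, as.raw(0))),
    dcm_element(0x0002, 0x0010, "UI", dcm_str_raw(UID_TRANSFER_EXPLICIT_LE, as.raw(0)))
  )
  # pixel data row-major (rows of columns), little-endian 16-bit
  px <- writeBin(as.integer(t(pixels) - intercept), raw(), size = 2,
                 endian = "little")
  body <- c(
    dcm_element(0x0008, 0x0016, "UI", dcm_str_raw(UID_SECONDARY_CAPTURE, as.raw(0))),
    dcm_element(0x0008, 0x0018, "UI", dcm_str_raw(sop_uid, as.raw(0))),
    dcm_element(0x0008, 0x0060, "CS", dcm_str_raw("CT")),
    dcm_element(0x0008, 0x0064, "CS", dcm_str_raw("SYN")),
    dcm_element(0x0010, 0x0010, "PN", dcm_str_raw("PHANTOM")),
    dcm_element(0x0010, 0x0020, "LO", dcm_str_raw(source_id)),
    dcm_element(0x0020, 0x000D, "UI", dcm_str_raw(dcm_new_uid(), as.raw(0))),
    dcm_element(0x0020, 0x000E, "UI", dcm_str_raw(dcm_new_uid(), as.raw(0))),
    dcm_element(0x0020, 0x0013, "IS", dcm_str_raw("1")),
    dcm_element(0x0028, 0x0002, "US", dcm_u16(1)),
    dcm_element(0x0028, 0x0004, "CS", dcm_str_raw("MONOCHROME2")),
    dcm_element(0x0028, 0x0010, "US", dcm_u16(nrow(pixels))),
    dcm_element(0x0028, 0x0011, "US", dcm_u16(ncol(pixels))),
    dcm_element(0x0028, 0x0030, "DS", dcm_str_raw(paste(spacing_mm, collapse = "\\"))),
    dcm_element(0x0028, 0x0100, "US", dcm_u16(16)),
    dcm_element(0x0028, 0x0101, "US", dcm_u16(16)),
    dcm_element(0x0028, 0x0102, "US", dcm_u16(15)),
    dcm_element(0x0028, 0x0103, "US", dcm_u16(0)),
    dcm_element(0x0028, 0x1050, "DS", dcm_str_raw(formatC(window_center, format = "fg", digits = 10))),
    dcm_element(0x0028, 0x1051, "DS", dcm_str_raw(formatC(window_width, format = "fg", digits = 10))),
    dcm_element(0x0028, 0x1052, "DS", dcm_str_raw(as.character(intercept))),
    dcm_element(0x0028, 0x1053, "DS", dcm_str_raw("1")),
    dcm_element(0x7FE0, 0x0010, "OW", px)
  )
  out <- c(raw(128), charToRaw("DICM"),
           dcm_element(0x0002, 0x0000, "UL", dcm_u32(length(meta))),
           meta, body)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop_lesionruler(
                    paste0("cannot open ", path, " for writing"), "lesionruler_io_error"))
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

# Parse every element of an explicit-VR little-endian DICOM file into a
# named list keyed "GGGGEEEE" (upper-case hex).
dcm_parse <- function(path) {
  if (!file.exists(path))
    stop_lesionruler(paste0("no such file: ", path), "lesionruler_io_error")
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 200 || rawToChar(bytes[129:132]) != "DICM")
    stop_lesionruler("not a DICOM file (missing DICM marker)", "lesionruler_format_error")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  pos <- 133L
  n <- length(bytes)
  els <- list()
  rd16 <- function(p) as.integer(bytes[p]) + 256L * as.integer(bytes[p + 1L])
  while (pos + 7L <= n) {
    group <- rd16(pos); elem <- rd16(pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop_lesionruler("unsupported DICOM encoding (implicit VR?)",
                       "lesionruler_format_error")
    if (vr %in% long_vrs) {
      len <- sum(as.integer(bytes[(pos + 8L):(pos + 11L)]) * c(1, 256, 65536, 16777216))
      vstart <- pos + 12L
    } else {
      len <- rd16(pos + 6L)
      vstart <- pos + 8L
    }
    if (len == 4294967295 || vr == "SQ")
      stop_lesionruler("sequences/undefined lengths not supported",
                       "lesionruler_format_error")
    if (vstart + len - 1L > n)
      stop_lesionruler("truncated DICOM element", "lesionruler_format_error")
    key <- sprintf("%04X%04X", group, elem)
    value <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0)
    els[[key]] <- list(vr = vr, value = value)
    if (key == "00020010") {
      ts <- trimws(rawToChar(value[value != as.raw(0)]))
      if (ts != UID_TRANSFER_EXPLICIT_LE)
        stop_lesionruler(paste0("unsupported transfer syntax: ", ts),
                         "lesionruler_format_error")
    }
    pos <- vstart + len
  }
  els
}

dcm_str <- function(els, key) {
  e <- els[[key]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$value[e$value != as.raw(0)]))
}

dcm_ds <- function(els, key) {
  s <- dcm_str(els, key)
  if (is.null(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dcm_us <- function(els, key) {
  e <- els[[key]]
  if (is.null(e)) return(NULL)
  readBin(e$value, "integer", n = 1, size = 2, signed = FALSE, endian = "little")
}
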