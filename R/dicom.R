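# Minimal DICOM reader for single-frame grayscale mammograms: uncompressed
# Explicit or Implicit VR little endian, honoring RescaleSlope/Intercept and
# PhotometricInterpretation (MONOCHROME1 is inverted so that bright always
# means dense tissue/muscle). This is deliberately narrow plumbing -- enough
# to ingest for-presentation FFDM exports -- not a general DICOM toolkit.

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1])
}
dcm_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1]) +
    65536 * as.numeric(raw[pos + 2]) + 16777216 * as.numeric(raw[pos + 3])
}
dcm_str <- function(raw, pos, len) {
  if (len == 0) return("")
  bytes <- raw[pos:(pos + len - 1)]
  trimws(rawToChar(bytes[bytes != as.raw(0)]))
}

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# parse one element at pos; returns list(group, elem, vr, val_pos, len, next_pos)
dcm_element <- function(raw, pos, explicit) {
  group <- dcm_u16(raw, pos)
  elem <- dcm_u16(raw, pos + 2)
  if (explicit) {
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% LONG_VRS) {
      len <- dcm_u32(raw, pos + 8)
      val_pos <- pos + 12
    } else {
      len <- dcm_u16(raw, pos + 6)
      val_pos <- pos + 8
    }
  } else {
    vr <- NA_character_
    len <- dcm_u32(raw, pos + 4)
    val_pos <- pos + 8
  }
  if (len == 4294967295) stop("unsupported DICOM: undefined-length element")
  list(group = group, elem = elem, vr = vr, val_pos = val_pos, len = len,
       next_pos = val_pos + len)
}

dcm_parse <- function(raw) {
  n <- length(raw)
  pos <- 1L
  if (n > 132 && rawToChar(raw[129:132]) == "DICM") pos <- 133L
  tags <- new.env(parent = emptyenv())
  # file meta group (0002) is always explicit VR little endian
  transfer_syntax <- "1.2.840.10008.1.2.1"
  meta_explicit <- TRUE
  explicit <- TRUE
  in_meta <- TRUE
  while (pos + 7 <= n) {
    el <- dcm_element(raw, pos, if (in_meta) meta_explicit else explicit)
    if (in_meta && el$group != 2L) {
      in_meta <- FALSE
      explicit <- !identical(transfer_syntax, "1.2.840.10008.1.2")
      if (!transfer_syntax %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        stop("unsupported DICOM transfer syntax: ", transfer_syntax)
      el <- dcm_element(raw, pos, explicit)
    }
    key <- sprintf("%04x,%04x", el$group, el$elem)
    if (key == "0002,0010") transfer_syntax <- dcm_str(raw, el$val_pos, el$len)
    assign(key, el, envir = tags)
    if (key == "7fe0,0010") break
    pos <- el$next_pos
  }
  list(tags = tags, raw = raw)
}

dcm_get_str <- function(p, key, default = NA_character_) {
  if (!exists(key, envir = p$tags)) return(default)
  el <- get(key, envir = p$tags)
  dcm_str(p$raw, el$val_pos, el$len)
}
dcm_get_us <- function(p, key, default = NA_integer_) {
  if (!exists(key, envir = p$tags)) return(default)
  el <- get(key, envir = p$tags)
  dcm_u16(p$raw, el$val_pos)
}
dcm_get_num <- function(p, key, default = NA_real_) {
  s <- dcm_get_str(p, key)
  if (is.na(s) || s == "") return(default)
  as.numeric(s)
}

#' Read a single-frame grayscale DICOM mammogram
#'
#' Supports uncompressed Explicit/Implicit VR little-endian files. Pixel
#' values are mapped through RescaleSlope/Intercept, inverted when the
#' photometric interpretation is MONOCHROME1 (so brighter always means
#' denser tissue), and normalized to \[0, 1\]. Laterality and view are taken
#' from the ImageLaterality and ViewPosition tags when present.
#'
#' @param path Path to the DICOM file.
#' @return A `mammogram`.
#' @export
read_dicom_mammogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  p <- dcm_parse(raw)
  if (!exists("7fe0,0010", envir = p$tags))
    stop("DICOM format error: no pixel data element")
  spp <- dcm_get_us(p, "0028,0002", 1L)
  if (!is.na(spp) && spp != 1L)
    stop("unsupported DICOM: color image (SamplesPerPixel > 1)")
  nframes <- dcm_get_num(p, "0028,0008", 1)
  if (!is.na(nframes) && nframes > 1)
    stop("unsupported DICOM: multi-frame image")
  rows <- dcm_get_us(p, "0028,0010")
  cols <- dcm_get_us(p, "0028,0011")
  if (is.na(rows) || is.na(cols)) stop("DICOM format error: missing Rows/Columns")
  bits <- dcm_get_us(p, "0028,0100", 16L)
  signed <- identical(dcm_get_us(p, "0028,0103", 0L), 1L)
  el <- get("7fe0,0010", envir = p$tags)
  npx <- rows * cols
  bytes <- bits %/% 8L
  if (el$len < npx * bytes) stop("DICOM format error: truncated pixel data")
  con <- p$raw[el$val_pos:(el$val_pos + npx * bytes - 1)]
  vals <- readBin(con, "integer", n = npx, size = bytes, signed = signed,
                  endian = "little")
  slope <- dcm_get_num(p, "0028,1053", 1)
  intercept <- dcm_get_num(p, "0028,1052", 0)
  vals <- vals * slope + intercept
  photometric <- dcm_get_str(p, "0028,0004", "MONOCHROME2")
  if (identical(photometric, "MONOCHROME1")) vals <- -vals
  px <- matrix(vals, nrow = rows, byrow = TRUE)
  lat <- dcm_get_str(p, "0020,0062", "")
  lat <- if (lat %in% c("L", "R")) lat else "unknown"
  view <- dcm_get_str(p, "0018,5101", "")
  view <- if (view %in% c("MLO", "CC")) view else "unknown"
  mammogram(px, laterality = lat, view = view,
            image_id = tools::file_path_sans_ext(basename(path)),
            normalize = TRUE)
}
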