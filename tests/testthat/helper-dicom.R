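# Byte-level writer for minimal single-frame Explicit-VR little-endian
# DICOM fixtures, so DICOM reading can be tested without any binary files
# in the repository.

u16le <- function(x) as.raw(c(x %% 256, x %/% 256))
u32le <- function(x) {
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

dcm_el_short <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) {
    pad <- if (vr %in% c("UI")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  c(u16le(group), u16le(elem), charToRaw(vr), u16le(length(value_raw)), value_raw)
}

dcm_el_ow <- function(group, elem, value_raw) {
  c(u16le(group), u16le(elem), charToRaw("OW"), as.raw(c(0, 0)),
    u32le(length(value_raw)), value_raw)
}

dcm_el_str <- function(group, elem, vr, s) dcm_el_short(group, elem, vr, charToRaw(s))
dcm_el_us <- function(group, elem, x) dcm_el_short(group, elem, "US", u16le(x))

# vals: integer matrix (rows x cols), unsigned 16-bit, row-major on disk
write_dicom_fixture <- function(path, vals, photometric = "MONOCHROME2",
                                laterality = "L", view = "MLO",
                                slope = 1, intercept = 0,
                                include_pixeldata = TRUE) {
  px16 <- as.integer(t(vals))  # row-major
  px_raw <- writeBin(px16, raw(), size = 2, endian = "little")
  # writeBin writes signed; values < 32768 in tests so this is exact
  body <- c(
    dcm_el_str(0x0008, 0x0060, "CS", "MG"),
    dcm_el_str(0x0018, 0x5101, "CS", view),
    dcm_el_str(0x0020, 0x0062, "CS", laterality),
    dcm_el_us(0x0028, 0x0002, 1),
    dcm_el_str(0x0028, 0x0004, "CS", photometric),
    dcm_el_us(0x0028, 0x0010, nrow(vals)),
    dcm_el_us(0x0028, 0x0011, ncol(vals)),
    dcm_el_us(0x0028, 0x0100, 16),
    dcm_el_us(0x0028, 0x0101, 16),
    dcm_el_us(0x0028, 0x0103, 0),
    dcm_el_str(0x0028, 0x1052, "DS", format(intercept)),
    dcm_el_str(0x0028, 0x1053, "DS", format(slope))
  )
  if (include_pixeldata) body <- c(body, dcm_el_ow(0x7FE0, 0x0010, px_raw))
  meta <- dcm_el_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  out <- c(rep(as.raw(0), 128), charToRaw("DICM"), meta, body)
  writeBin(out, path)
  invisible(path)
}
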