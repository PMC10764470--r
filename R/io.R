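# Raster I/O: PNG/TIFF masks and images, plus a simple boundary overlay
# renderer. Masks are written as 8-bit PNG with 0 = background, 255 =
# region; write_mask/read_mask round-trip bit-exactly.

raster_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext))
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    ch <- min(nch, 3)
    for (k in seq_len(ch - 1)) {
      if (!isTRUE(all.equal(arr[, , k], arr[, , k + 1])))
        stop("unsupported input: RGB image with unequal channels")
    }
    arr <- arr[, , 1]
  }
  arr
}

#' Read a binary mask from PNG or TIFF
#'
#' Nonzero pixels map to `TRUE`. 8- and 16-bit single-channel rasters are
#' accepted; RGB files are accepted only when all channels are equal.
#'
#' @param path Path to the mask file.
#' @param semantics Mask semantics label, see [binary_mask()].
#' @export
read_mask <- function(path, semantics = "truth_pectoral") {
  arr <- raster_gray(path)
  binary_mask(arr > 0, semantics,
              image_id = tools::file_path_sans_ext(basename(path)))
}

#' Write a binary mask as an 8-bit PNG
#'
#' @param mask A `binary_mask` or logical matrix.
#' @param path Output path (`.png`).
#' @export
write_mask <- function(mask, path) {
  v <- if (inherits(mask, "binary_mask")) mask$values else mask
  stopifnot(is.logical(v))
  png::writePNG(v * 1.0, path)
  invisible(path)
}

#' Read a mammogram from DICOM, PNG or TIFF
#'
#' Dispatches on the file extension; raster inputs are normalized to
#' \[0, 1\] per image.
#'
#' @param path Input file.
#' @param laterality,view Metadata for raster inputs (DICOM files carry
#'   their own tags).
#' @export
read_mammogram <- function(path, laterality = "unknown", view = "unknown") {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom"))
    return(read_dicom_mammogram(path))
  arr <- raster_gray(path)
  mammogram(arr, laterality = laterality, view = view,
            image_id = tools::file_path_sans_ext(basename(path)),
            normalize = TRUE)
}

#' Write an image with the mask perimeter drawn in red
#'
#' @param img A `mammogram` (or numeric matrix in \[0,1\]).
#' @param mask A `binary_mask` (or logical matrix) in the same frame.
#' @param path Output PNG path.
#' @export
write_overlay <- function(img, mask, path) {
  px <- if (inherits(img, "mammogram")) img$pixels else img
  v <- if (inherits(mask, "binary_mask")) mask$values else mask
  stopifnot(identical(dim(px), dim(v)))
  inner <- shift_mat(v, 1, 0, FALSE) & shift_mat(v, -1, 0, FALSE) &
           shift_mat(v, 0, 1, FALSE) & shift_mat(v, 0, -1, FALSE)
  perim <- v & !inner
  rgb <- array(px, c(dim(px), 3))
  r <- rgb[, , 1]; g <- rgb[, , 2]; b <- rgb[, , 3]
  r[perim] <- 1; g[perim] <- 0; b[perim] <- 0
  rgb[, , 1] <- r; rgb[, , 2] <- g; rgb[, , 3] <- b
  png::writePNG(rgb, path)
  invisible(path)
}
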