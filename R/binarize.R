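# Two-stage global thresholding (Otsu): first separate the imaged tissue
# from the dark background, then separate the highly bright pixels (pectoral
# muscle, dense tissue) from the rest of the tissue, using only intensities
# inside the foreground for the second threshold.

otsu_threshold <- function(values) {
  # EBImage's histogram-based Otsu; accepts any numeric array in [0,1]
  EBImage::otsu(matrix(values, ncol = 1), range = c(0, 1), levels = 256)
}

#' Foreground (imaged tissue) binarization
#'
#' Thresholds the whole image with a global threshold (Otsu by default) and
#' keeps the largest 4-connected component, so burned-in labels or markers
#' detached from the breast are dropped.
#'
#' @param img A canonical-orientation `mammogram`.
#' @param cfg A [pipeline_config()].
#' @return A `binary_mask` with semantics `"foreground"`; the threshold used
#'   is attached as attribute `"threshold"`.
#' @export
binarize_foreground <- function(img, cfg = pipeline_config()) {
  stopifnot(inherits(img, "mammogram"))
  px <- img$pixels
  thr <- if (cfg$foreground_threshold_method == "otsu") otsu_threshold(px)
         else cfg$fixed_thresholds[1]
  raw <- px > thr
  if (!any(raw)) stop("degenerate input: empty foreground at threshold ", thr)
  fg <- largest_component(raw, connectivity = 4)
  out <- binary_mask(fg, "foreground", img$image_id)
  attr(out, "threshold") <- thr
  out
}

#' Bright-region binarization and pectoral candidate selection
#'
#' Thresholds the intensities inside the foreground with a second global
#' threshold (Otsu restricted to foreground pixels by default). Among the
#' resulting bright components, the one touching the chest-wall corner
#' (column 1, upper half of the image) is retained as the pectoral
#' candidate; other bright components (dense tissue) are returned separately.
#' When no component touches the corner the candidate is empty and
#' `no_pectoral_found` is flagged -- a valid outcome (e.g. CC views), not an
#' error.
#'
#' @param img A canonical-orientation `mammogram`.
#' @param foreground Foreground `binary_mask` from [binarize_foreground()].
#' @param cfg A [pipeline_config()].
#' @return List with `candidate` (`binary_mask`, semantics `"bright"`),
#'   `other_bright` (`binary_mask`), `threshold`, and `no_pectoral_found`.
#' @export
binarize_bright <- function(img, foreground, cfg = pipeline_config()) {
  stopifnot(inherits(img, "mammogram"), inherits(foreground, "binary_mask"))
  fg <- foreground$values
  if (!any(fg)) stop("foreground must be nonempty")
  px <- img$pixels
  thr <- if (cfg$bright_threshold_method == "otsu_within_foreground")
    otsu_threshold(px[fg]) else cfg$fixed_thresholds[2]
  bright <- fg & (px > thr)
  lab <- label_components(bright, connectivity = 4)
  corner_rows <- seq_len(ceiling(nrow(px) / 2))
  corner_ids <- setdiff(unique(lab[corner_rows, 1]), 0L)
  if (length(corner_ids) == 0) {
    empty <- binary_mask(bright & FALSE, "bright", img$image_id)
    return(list(candidate = empty,
                other_bright = binary_mask(bright, "bright", img$image_id),
                threshold = thr, no_pectoral_found = TRUE))
  }
  sizes <- tabulate(lab, nbins = max(lab))
  cand_id <- corner_ids[which.max(sizes[corner_ids])]
  cand <- lab == cand_id
  list(candidate = binary_mask(cand, "bright", img$image_id),
       other_bright = binary_mask(bright & !cand, "bright", img$image_id),
       threshold = thr, no_pectoral_found = FALSE)
}
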