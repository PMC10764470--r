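# The full segmentation pipeline: canonicalize orientation, optionally
# downscale to a working width, binarize (foreground, then bright within
# foreground), run Canny on the binarized composite, extract the boundary
# along the candidate perimeter, smooth/interpolate it robustly, map the
# curve back to native resolution and rasterize the pectoral mask.

#' Pipeline configuration
#'
#' @param working_width Images wider than this are downscaled (bilinear) to
#'   this many columns before processing; the fitted boundary -- not the
#'   mask -- is then mapped back to native resolution. 0 disables downscaling.
#' @param canny A [canny_params()] object. The default sigma is calibrated
#'   to the default working width.
#' @param foreground_threshold_method `"otsu"` or `"fixed"`.
#' @param bright_threshold_method `"otsu_within_foreground"` or `"fixed"`.
#' @param fixed_thresholds Two intensities in \[0,1\] (foreground, bright),
#'   used only with the fixed methods.
#' @param smoother A [smoother_config()].
#' @param min_pectoral_rows Minimum observed boundary rows (at working
#'   resolution) before declaring the image pectoral-free.
#' @param jump_limit_frac Fraction of the working width treated as the
#'   largest plausible column change of the boundary between consecutive
#'   rows; larger jumps mark the row missing.
#' @param canny_input `"binary"` (default: Canny runs on the binarized
#'   foreground/bright composite) or `"grayscale"` (runs on the image).
#' @export
pipeline_config <- function(working_width = 512,
                            canny = canny_params(),
                            foreground_threshold_method = c("otsu", "fixed"),
                            bright_threshold_method = c("otsu_within_foreground", "fixed"),
                            fixed_thresholds = c(0.1, 0.6),
                            smoother = smoother_config(),
                            min_pectoral_rows = 10,
                            jump_limit_frac = 0.03,
                            canny_input = c("binary", "grayscale")) {
  stopifnot(working_width == 0 || working_width >= 64,
            length(fixed_thresholds) == 2,
            all(fixed_thresholds >= 0 & fixed_thresholds <= 1),
            min_pectoral_rows >= 1, jump_limit_frac > 0)
  structure(list(working_width = working_width, canny = canny,
                 foreground_threshold_method = match.arg(foreground_threshold_method),
                 bright_threshold_method = match.arg(bright_threshold_method),
                 fixed_thresholds = fixed_thresholds, smoother = smoother,
                 min_pectoral_rows = min_pectoral_rows,
                 jump_limit_frac = jump_limit_frac,
                 canny_input = match.arg(canny_input)),
            class = "pipeline_config")
}

resize_bilinear <- function(m, n_rows, n_cols) {
  as.matrix(EBImage::imageData(EBImage::resize(EBImage::Image(m),
                                               w = n_rows, h = n_cols)))
}

# pixel-center coordinate maps between native and working grids
to_native <- function(x_work, scale) (x_work - 0.5) / scale + 0.5
to_work <- function(x_native, scale) (x_native - 0.5) * scale + 0.5

# number of pectoral columns in a row: strict inequality against the
# boundary after half-up rounding (0-based convention), i.e. floor(b + 0.5)
# pectoral columns where b is the 0-based boundary position
pectoral_cols <- function(col_1based) {
  floor((col_1based - 1) + 0.5 + 1e-9)
}

rasterize_pectoral <- function(boundary_native, n_rows, n_cols) {
  pect <- matrix(FALSE, n_rows, n_cols)
  rows <- boundary_native$rows
  cols <- boundary_native$cols
  for (i in seq_along(rows)) {
    k <- min(max(pectoral_cols(cols[i]), 0L), n_cols)
    if (k >= 1) pect[rows[i], seq_len(k)] <- TRUE
  }
  pect
}

empty_result <- function(img, fg_native, flags) {
  n_rows <- img$n_rows; n_cols <- img$n_cols
  fgv <- if (is.null(fg_native)) matrix(FALSE, n_rows, n_cols) else fg_native
  pect <- matrix(FALSE, n_rows, n_cols)
  list(pectoral = pect, breast = fgv, foreground = fgv,
       boundary = boundary_curve(NA, NA, numeric(0), no_pectoral_found = TRUE),
       flags = flags)
}

#' Segment the pectoral muscle in an MLO mammogram
#'
#' Runs the complete pipeline and returns masks in the image's original
#' orientation. The pectoral and breast masks always partition the
#' foreground: `pectoral | breast == foreground` and
#' `pectoral & breast == FALSE` everywhere. When no pectoral is found the
#' pectoral mask is empty and the breast mask equals the foreground.
#'
#' @param img A `mammogram`.
#' @param cfg A [pipeline_config()].
#' @return A `segmentation_result`: list with `binary_mask`s `pectoral_mask`,
#'   `breast_mask`, `foreground_mask`; `boundary` (native resolution,
#'   canonical chest-wall-left frame); `pectoral_area`; `flags` (character
#'   subset of `no_pectoral_found`, `low_support`, `ambiguous_orientation`);
#'   and `diagnostics` (thresholds, smoothing level, support).
#' @export
segment_pectoral <- function(img, cfg = pipeline_config()) {
  stopifnot(inherits(img, "mammogram"), inherits(cfg, "pipeline_config"))
  if (isTRUE(img$degenerate)) stop("degenerate input: constant image")
  img <- suppressWarnings(normalize_orientation(img))
  flags <- character(0)
  if (isTRUE(img$ambiguous_orientation)) flags <- c(flags, "ambiguous_orientation")

  n_rows <- img$n_rows; n_cols <- img$n_cols
  scale <- 1
  work <- img
  if (cfg$working_width > 0 && n_cols > cfg$working_width) {
    scale <- cfg$working_width / n_cols
    wpx <- resize_bilinear(img$pixels, max(3L, round(n_rows * scale)),
                           cfg$working_width)
    wpx[wpx < 0] <- 0; wpx[wpx > 1] <- 1
    work <- mammogram(wpx, img$laterality, img$view, "left",
                      img$image_id, normalize = FALSE)
  }

  fg_work <- binarize_foreground(work, cfg)
  fg_native <- if (scale == 1) fg_work else binarize_foreground(img, cfg)
  diag_info <- list(foreground_threshold = attr(fg_work, "threshold"),
                    working_width = ncol(work$pixels), scale = scale)

  finish <- function(res, boundary, s_used = NA_real_, support = NA_real_) {
    pect <- res$pectoral & fg_native$values
    breast <- fg_native$values & !pect
    out <- list(
      pectoral_mask = restore_orientation(binary_mask(pect, "pectoral", img$image_id), img),
      breast_mask = restore_orientation(binary_mask(breast, "breast_tissue", img$image_id), img),
      foreground_mask = restore_orientation(binary_mask(fg_native$values, "foreground", img$image_id), img),
      boundary = boundary,
      pectoral_area = sum(pect),
      flags = res$flags,
      diagnostics = c(diag_info, list(s_used = s_used, support_fraction = support,
                                      flags = res$flags))
    )
    class(out) <- "segmentation_result"
    out
  }

  br <- binarize_bright(work, fg_work, cfg)
  diag_info$bright_threshold <- br$threshold
  if (br$no_pectoral_found) {
    res <- empty_result(img, fg_native$values, c(flags, "no_pectoral_found"))
    return(finish(res, res$boundary))
  }

  canny_in <- if (cfg$canny_input == "binary") {
    0.5 * fg_work$values + 0.5 * br$candidate$values
  } else work$pixels
  edges <- canny_edges(canny_in, cfg$canny)

  jump_limit <- max(2, round(cfg$jump_limit_frac * ncol(work$pixels)))
  bc <- extract_boundary(edges, br$candidate, jump_limit = jump_limit,
                         min_pectoral_rows = cfg$min_pectoral_rows)
  if (bc$no_pectoral_found) {
    res <- empty_result(img, fg_native$values, c(flags, "no_pectoral_found"))
    return(finish(res, res$boundary))
  }
  if (bc$support_fraction < 0.5) flags <- c(flags, "low_support")

  fit <- robust_smooth(bc$columns, cfg$smoother)
  smoothed <- boundary_curve(bc$row_start, bc$row_end, fit$z)
  smoothed$support_fraction <- bc$support_fraction

  # map the fitted curve (working grid) onto native rows
  r_lo <- max(1L, ceiling(to_native(bc$row_start - 0.5, scale)))
  r_hi <- min(n_rows, floor(to_native(bc$row_end + 0.5, scale)))
  rows_n <- r_lo:r_hi
  col_w <- stats::approx(x = bc$row_start:bc$row_end, y = fit$z,
                         xout = to_work(rows_n, scale), rule = 2)$y
  cols_n <- to_native(col_w, scale)
  native_curve <- boundary_curve(r_lo, r_hi, cols_n)
  native_curve$support_fraction <- bc$support_fraction

  pect <- rasterize_pectoral(list(rows = rows_n, cols = cols_n), n_rows, n_cols)
  res <- list(pectoral = pect, flags = flags)
  finish(res, native_curve, s_used = fit$s_used, support = bc$support_fraction)
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result '%s'> pectoral area %d px%s\n",
              x$pectoral_mask$image_id, x$pectoral_area,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]") else ""))
  invisible(x)
}
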