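#' Mammogram image container
#'
#' Wraps a 2-D grayscale intensity matrix together with the metadata the
#' segmentation pipeline needs: laterality, view, which column border the
#' chest wall sits on, and an image identifier. Intensities are stored as
#' doubles normalized to \[0, 1\]; row 1 is the superior (top) edge.
#'
#' @param pixels Numeric matrix of intensities. Values are rescaled to
#'   \[0, 1\] unless `normalize = FALSE`.
#' @param laterality `"L"`, `"R"` or `"unknown"`.
#' @param view `"MLO"`, `"CC"` or `"unknown"`.
#' @param chest_wall_side `"left"`, `"right"` or `NA` (unknown; inferred
#'   later from border intensities).
#' @param image_id Opaque identifier string.
#' @param normalize Rescale intensities to \[0, 1\] (min/max per image)?
#'   A constant image normalizes to all zeros and is flagged degenerate.
#' @return An object of class `mammogram`.
#' @export
mammogram <- function(pixels, laterality = "unknown", view = "unknown",
                      chest_wall_side = NA_character_, image_id = "img",
                      normalize = TRUE) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!all(is.finite(pixels))) stop("pixels must be finite")
  laterality <- match.arg(laterality, c("L", "R", "unknown"))
  view <- match.arg(view, c("MLO", "CC", "unknown"))
  degenerate <- FALSE
  px <- pixels
  if (normalize) {
    rng <- range(px)
    if (rng[2] > rng[1]) {
      px <- (px - rng[1]) / (rng[2] - rng[1])
    } else {
      px <- array(0, dim(px))
      degenerate <- TRUE
    }
  } else {
    if (any(px < 0 | px > 1)) stop("pixels must lie in [0, 1] when normalize = FALSE")
    if (max(px) == min(px)) degenerate <- TRUE
  }
  structure(list(
    pixels = px,
    n_rows = nrow(px), n_cols = ncol(px),
    laterality = laterality, view = view,
    chest_wall_side = chest_wall_side,
    image_id = image_id,
    flipped = FALSE,
    degenerate = degenerate
  ), class = "mammogram")
}

#' @export
print.mammogram <- function(x, ...) {
  cat(sprintf("<mammogram '%s'> %d x %d, laterality %s, view %s%s\n",
              x$image_id, x$n_rows, x$n_cols, x$laterality, x$view,
              if (isTRUE(x$flipped)) " (flipped to canonical)" else ""))
  invisible(x)
}

#' Binary mask aligned to an image
#'
#' @param values Logical matrix.
#' @param semantics One of `"foreground"`, `"bright"`, `"pectoral"`,
#'   `"breast_tissue"`, `"truth_pectoral"`.
#' @param image_id Identifier of the parent image.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(values, semantics = "foreground", image_id = "img") {
  stopifnot(is.matrix(values), is.logical(values))
  semantics <- match.arg(semantics, c("foreground", "bright", "pectoral",
                                      "breast_tissue", "truth_pectoral"))
  structure(list(values = values, n_rows = nrow(values), n_cols = ncol(values),
                 semantics = semantics, image_id = image_id),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask '%s'> %d x %d (%s), area %d\n",
              x$image_id, x$n_rows, x$n_cols, x$semantics, mask_area(x)))
  invisible(x)
}

#' Number of true pixels in a mask
#' @param mask A `binary_mask` or logical matrix.
#' @export
mask_area <- function(mask) {
  v <- if (inherits(mask, "binary_mask")) mask$values else mask
  sum(v)
}

flip_lr <- function(m) m[, ncol(m):1, drop = FALSE]

#' Canonicalize chest-wall orientation
#'
#' Returns the image with the chest wall at column 1 (left edge). The side
#' is taken from `chest_wall_side` when recorded; otherwise the column
#' border with the greater mean intensity is taken as the chest wall. When
#' the two border means differ by less than 5% (relative) and no metadata is
#' available, the image is left unflipped and flagged ambiguous. Applying
#' the function twice restores the original orientation (`flipped` toggles).
#'
#' @param img A `mammogram`.
#' @param border_cols Number of border columns averaged by the intensity
#'   heuristic.
#' @return The `mammogram` in canonical orientation, with `flipped` and
#'   `ambiguous_orientation` recorded.
#' @export
normalize_orientation <- function(img, border_cols = 8) {
  stopifnot(inherits(img, "mammogram"))
  side <- img$chest_wall_side
  ambiguous <- FALSE
  if (is.na(side)) {
    k <- min(border_cols, ncol(img$pixels))
    left <- mean(img$pixels[, seq_len(k)])
    right <- mean(img$pixels[, ncol(img$pixels) - seq_len(k) + 1])
    denom <- max(left, right)
    if (denom <= 0 || abs(left - right) / denom < 0.05) {
      if (img$laterality == "unknown") {
        warning("ambiguous chest-wall side; assuming no flip")
        ambiguous <- TRUE
        side <- "left"
      } else {
        # last resort: laterality tag, assuming chest wall on the same side
        side <- if (img$laterality == "L") "left" else "right"
      }
    } else {
      side <- if (left >= right) "left" else "right"
    }
  }
  if (side == "right") {
    img$pixels <- flip_lr(img$pixels)
    img$flipped <- !isTRUE(img$flipped)
  }
  img$chest_wall_side <- "left"
  img$ambiguous_orientation <- ambiguous
  img
}

#' Map a canonical-frame mask back to the original orientation
#'
#' @param mask A `binary_mask` produced in the canonical frame.
#' @param img The canonicalized `mammogram` the mask belongs to (its
#'   `flipped` field says whether a left-right flip was applied).
#' @return The mask in the original acquisition orientation.
#' @export
restore_orientation <- function(mask, img) {
  stopifnot(inherits(mask, "binary_mask"), inherits(img, "mammogram"))
  if (isTRUE(img$flipped)) mask$values <- flip_lr(mask$values)
  mask
}
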