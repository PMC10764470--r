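# Canny chain: Gaussian pre-smoothing, Sobel gradients, non-maximum
# suppression with 8-direction quantization, double-threshold hysteresis.
# Thresholds are data-driven: the strong threshold is a quantile of the
# nonzero gradient magnitudes, the weak one a fixed fraction of it.

#' Canny detector parameters
#'
#' @param sigma Gaussian pre-smoothing scale in pixels (> 0).
#' @param high_quantile Quantile of nonzero gradient magnitudes used as the
#'   strong-edge threshold, in (0, 1].
#' @param low_fraction Weak threshold as a fraction of the strong one,
#'   in (0, 1].
#' @export
canny_params <- function(sigma = 2, high_quantile = 0.90, low_fraction = 0.40) {
  stopifnot(sigma > 0, high_quantile > 0, high_quantile <= 1,
            low_fraction > 0, low_fraction <= 1)
  structure(list(sigma = sigma, high_quantile = high_quantile,
                 low_fraction = low_fraction), class = "canny_params")
}

# shift a matrix by (dr, dc), filling vacated cells with `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# separable 1-D convolution along rows (dim = 1) or columns (dim = 2),
# replicate border handling
conv1d <- function(m, kernel, dim) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- if (dim == 1) nrow(m) else ncol(m)
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(kernel)) {
    d <- k - r - 1L
    idx <- pmin(pmax(seq_len(n) + d, 1L), n)
    out <- out + kernel[k] * (if (dim == 1) m[idx, , drop = FALSE]
                              else m[, idx, drop = FALSE])
  }
  out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur with replicate borders
#' @param m Numeric matrix.
#' @param sigma Smoothing scale in pixels.
#' @export
gaussian_blur <- function(m, sigma) {
  k <- gaussian_kernel(sigma)
  conv1d(conv1d(m, k, 1), k, 2)
}

sobel_gradients <- function(m) {
  # gx: derivative along columns, gy: along rows (row 1 = top)
  gx <- conv1d(conv1d(m, c(1, 2, 1), 1), c(-1, 0, 1), 2)
  gy <- conv1d(conv1d(m, c(1, 2, 1), 2), c(-1, 0, 1), 1)
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# non-maximum suppression: keep pixels maximal along the quantized gradient
# direction; ties broken asymmetrically so plateaus stay one pixel thin
nms_thin <- function(mag, gx, gy) {
  ang <- atan2(gy, gx) * 180 / pi
  ang <- ang %% 180
  bin <- integer(length(ang))
  dim(bin) <- dim(ang)
  bin[ang < 22.5 | ang >= 157.5] <- 0L    # column direction
  bin[ang >= 22.5 & ang < 67.5] <- 1L     # diagonal (+r, +c)
  bin[ang >= 67.5 & ang < 112.5] <- 2L    # row direction
  bin[ang >= 112.5 & ang < 157.5] <- 3L   # anti-diagonal (+r, -c)
  offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  for (b in 0:3) {
    o <- offs[[b + 1L]]
    npos <- shift_mat(mag, -o[1], -o[2])   # value at (r + dr, c + dc)
    nneg <- shift_mat(mag, o[1], o[2])
    keep_b <- (mag >= npos) & (mag > nneg)
    keep <- keep | (bin == b & keep_b)
  }
  keep & (mag > 0)
}

#' Canny edge detection
#'
#' Runs the full chain on a numeric matrix (grayscale image or a binarized
#' composite): Gaussian smoothing, Sobel gradients, non-maximum suppression
#' with 8-direction quantization, and double-threshold hysteresis linking
#' (weak edge pixels are kept only in 8-connected components that contain a
#' strong pixel). Constant input yields an empty edge map.
#'
#' @param m Numeric matrix with finite entries.
#' @param params A [canny_params()] object.
#' @return An `edge_map`: list with logical `values` and numeric
#'   `gradient_magnitude`, both the shape of `m`.
#' @export
canny_edges <- function(m, params = canny_params()) {
  stopifnot(is.matrix(m), is.numeric(m), all(is.finite(m)),
            inherits(params, "canny_params"))
  sm <- gaussian_blur(m, params$sigma)
  g <- sobel_gradients(sm)
  empty <- function() structure(list(values = matrix(FALSE, nrow(m), ncol(m)),
                                     gradient_magnitude = g$mag,
                                     strong_threshold = NA_real_,
                                     weak_threshold = NA_real_),
                                class = "edge_map")
  nz <- g$mag[g$mag > 0]
  if (length(nz) == 0) return(empty())
  strong <- stats::quantile(nz, params$high_quantile, names = FALSE)
  weak <- params$low_fraction * strong
  if (strong <= 0) return(empty())
  thin <- nms_thin(g$mag, g$gx, g$gy)
  cand <- thin & (g$mag >= weak)
  strong_px <- thin & (g$mag >= strong)
  if (!any(strong_px)) return(empty())
  lab <- label_components(cand, connectivity = 8)
  keep_ids <- unique(lab[strong_px])
  values <- cand & matrix(lab %in% keep_ids, nrow(lab), ncol(lab))
  structure(list(values = values, gradient_magnitude = g$mag,
                 strong_threshold = strong, weak_threshold = weak),
            class = "edge_map")
}
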