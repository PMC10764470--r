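# Deterministic synthetic-mammogram phantoms with analytic ground truth.
# The breast is a half-ellipse against the chest-wall edge; the pectoral
# muscle is a wedge whose boundary column is a quadratic function of the
# row; dense-tissue distractors are smooth bright bumps; edge-break bands
# erase the pectoral/breast contrast near the boundary. Identical seeds
# yield bit-identical phantoms.

#' Phantom specification
#'
#' The default geometry and intensities model an MLO view at 1/8 linear
#' scale of a 3328 x 2560 for-presentation mammogram: a bright pectoral
#' wedge in the chest-wall corner, mid-intensity breast tissue, dark
#' background.
#'
#' @param n_rows,n_cols Image size in pixels.
#' @param side `"L"` or `"R"` (right phantoms are mirror images).
#' @param pectoral List: `present`, `top_column` (0-based boundary column at
#'   row 0), `exit_row` (0-based row where the boundary meets the chest
#'   wall), `curvature` (quadratic bowing in pixels, positive bows away from
#'   the chest wall).
#' @param intensities List: `background`, `breast`, `pectoral`, each in
#'   \[0,1\] and strictly increasing in that order.
#' @param noise_sd Additive Gaussian noise sd (clipped to \[0,1\]).
#' @param dense_blobs List of `c(center_row, center_col, radius, amplitude)`
#'   bright bumps inside the breast.
#' @param edge_breaks List of `c(row_start, row_end)` bands (1-based rows)
#'   where a 5-pixel strip on the pectoral side of the boundary is reset to
#'   breast intensity, simulating dense tissue abutting the muscle.
#' @param seed Integer seed; the phantom is a pure function of the spec.
#' @export
phantom_spec <- function(n_rows = 416, n_cols = 320, side = "L",
                         pectoral = list(present = TRUE, top_column = 176,
                                         exit_row = 300, curvature = 0),
                         intensities = list(background = 0.02, breast = 0.45,
                                            pectoral = 0.85),
                         noise_sd = 0, dense_blobs = list(),
                         edge_breaks = list(), seed = 7) {
  side <- match.arg(side, c("L", "R"))
  stopifnot(n_rows >= 32, n_cols >= 32,
            intensities$pectoral > intensities$breast,
            intensities$breast > intensities$background,
            noise_sd >= 0)
  if (isTRUE(pectoral$present)) {
    stopifnot(pectoral$exit_row > 0, pectoral$exit_row <= n_rows,
              pectoral$top_column > 0, pectoral$top_column < n_cols)
  }
  structure(list(n_rows = n_rows, n_cols = n_cols, side = side,
                 pectoral = pectoral, intensities = intensities,
                 noise_sd = noise_sd, dense_blobs = dense_blobs,
                 edge_breaks = edge_breaks, seed = seed),
            class = "phantom_spec")
}

# 0-based boundary column at 0-based row r
phantom_boundary_fun <- function(spec) {
  p <- spec$pectoral
  function(r) {
    t <- r / p$exit_row
    p$top_column * (1 - t) + p$curvature * t * (1 - t)
  }
}

#' Analytic pectoral wedge area of a phantom spec
#'
#' Integral of the boundary column over the rows it spans:
#' `top_column * exit_row / 2 + curvature * exit_row / 6` pixels.
#' @param spec A [phantom_spec()].
#' @export
analytic_wedge_area <- function(spec) {
  if (!isTRUE(spec$pectoral$present)) return(0)
  p <- spec$pectoral
  p$top_column * p$exit_row / 2 + p$curvature * p$exit_row / 6
}

#' Generate a synthetic mammogram phantom
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom`: list with `image` (a `mammogram`), `truth_pectoral`
#'   and `truth_foreground` (`binary_mask`s in the phantom's own
#'   orientation), `boundary_true` (canonical chest-wall-left frame), and
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols
  ints <- spec$intensities
  r0 <- matrix(seq_len(nr) - 1, nr, nc)          # 0-based row at pixel center
  c0 <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)

  # breast: half-ellipse hugging the chest wall (column 0)
  cr <- 0.40 * nr; ar <- 0.78 * nr; ac <- 0.82 * nc
  fg <- ((r0 - cr) / ar)^2 + (c0 / ac)^2 <= 1

  pect <- matrix(FALSE, nr, nc)
  bfun <- NULL
  if (isTRUE(spec$pectoral$present)) {
    bfun <- phantom_boundary_fun(spec)
    last_row <- min(nr, ceiling(spec$pectoral$exit_row))
    for (r in seq_len(last_row)) {
      b <- bfun(r - 1)
      if (b <= 0) next
      k <- min(nc, pectoral_cols(b + 1))         # same rounding as pipeline
      if (k >= 1) pect[r, seq_len(k)] <- TRUE
    }
    pect <- pect & fg
  }

  px <- matrix(ints$background, nr, nc)
  px[fg] <- ints$breast
  px[pect] <- ints$pectoral

  for (blob in spec$dense_blobs) {
    d2 <- (r0 - blob[1])^2 + (c0 - blob[2])^2
    bump <- blob[4] * exp(-d2 / (2 * (blob[3] / 2)^2))
    px <- px + bump * fg
  }

  for (band in spec$edge_breaks) {
    if (is.null(bfun)) break
    rows <- max(1, band[1]):min(nr, band[2], ceiling(spec$pectoral$exit_row))
    for (r in rows) {
      k <- pectoral_cols(bfun(r - 1) + 1)
      if (k >= 1) px[r, max(1, k - 4):k] <- ints$breast
    }
  }

  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    px <- px + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
  }
  px[px < 0] <- 0; px[px > 1] <- 1

  wall <- "left"
  if (spec$side == "R") {
    px <- flip_lr(px); fg <- flip_lr(fg); pect <- flip_lr(pect)
    wall <- "right"
  }
  id <- sprintf("phantom_%s_seed%d", spec$side, spec$seed)
  img <- mammogram(px, laterality = spec$side, view = "MLO",
                   chest_wall_side = wall, image_id = id, normalize = FALSE)

  btrue <- if (isTRUE(spec$pectoral$present)) {
    last_row <- min(nr, ceiling(spec$pectoral$exit_row))
    boundary_curve(1, last_row, bfun(seq_len(last_row) - 1) + 1)
  } else boundary_curve(NA, NA, numeric(0), no_pectoral_found = TRUE)

  structure(list(image = img,
                 truth_pectoral = binary_mask(pect, "truth_pectoral", id),
                 truth_foreground = binary_mask(fg, "foreground", id),
                 boundary_true = btrue, spec = spec),
            class = "phantom")
}

#' Cohort parameter ranges
#'
#' Ranges from which [generate_cohort()] draws per-phantom geometry.
#' `right_area_inflation` scales the linear dimensions of right-side wedges
#' by its square root, so right pectoral areas are on average that factor
#' larger -- mirroring the left/right asymmetry seen in screening cohorts.
#'
#' @param top_column_frac,exit_row_frac Uniform ranges, as fractions of the
#'   image width/height.
#' @param curvature Uniform range in pixels.
#' @param noise_sd Noise level applied to every phantom.
#' @param right_area_inflation Mean right/left wedge-area ratio.
#' @param edge_break_rows `NULL`, or an integer range `c(lo, hi)` for the
#'   length of one randomly placed edge-break band per phantom.
#' @param blob_prob Probability of adding one bright dense-tissue blob
#'   bridging the boundary.
#' @export
cohort_variability <- function(top_column_frac = c(0.45, 0.62),
                               exit_row_frac = c(0.60, 0.80),
                               curvature = c(-8, 8),
                               noise_sd = 0,
                               right_area_inflation = 1.10,
                               edge_break_rows = NULL,
                               blob_prob = 0) {
  stopifnot(length(top_column_frac) == 2, length(exit_row_frac) == 2,
            right_area_inflation > 0, blob_prob >= 0, blob_prob <= 1)
  structure(list(top_column_frac = top_column_frac,
                 exit_row_frac = exit_row_frac, curvature = curvature,
                 noise_sd = noise_sd,
                 right_area_inflation = right_area_inflation,
                 edge_break_rows = edge_break_rows, blob_prob = blob_prob),
            class = "cohort_variability")
}

#' Generate a paired left/right phantom cohort
#'
#' Draws `n_per_side` phantom specs per side from `variability`,
#' deterministically under `seed`, and renders them (or returns the specs
#' only with `render = FALSE`, e.g. for area studies at large n).
#'
#' @param n_per_side Number of phantoms per side (>= 1).
#' @param seed Integer seed for the cohort draw.
#' @param variability A [cohort_variability()].
#' @param n_rows,n_cols Phantom size.
#' @param render Render images (`TRUE`) or return specs only.
#' @return List of `phantom` objects (or `phantom_spec`s), lefts then
#'   rights, ids `ph<k>_L` / `ph<k>_R`.
#' @export
generate_cohort <- function(n_per_side, seed = 1,
                            variability = cohort_variability(),
                            n_rows = 416, n_cols = 320, render = TRUE) {
  stopifnot(n_per_side >= 1, inherits(variability, "cohort_variability"))
  v <- variability
  set.seed(seed)
  out <- list()
  for (side in c("L", "R")) {
    infl <- if (side == "R") sqrt(v$right_area_inflation) else 1
    for (k in seq_len(n_per_side)) {
      top <- stats::runif(1, v$top_column_frac[1], v$top_column_frac[2]) * n_cols * infl
      exitr <- stats::runif(1, v$exit_row_frac[1], v$exit_row_frac[2]) * n_rows * infl
      curv <- stats::runif(1, v$curvature[1], v$curvature[2])
      exitr <- min(exitr, n_rows)
      top <- min(top, n_cols - 1)
      breaks <- list()
      if (!is.null(v$edge_break_rows)) {
        len <- sample(v$edge_break_rows[1]:v$edge_break_rows[2], 1)
        start <- sample(seq(10, max(11, floor(exitr) - len - 10)), 1)
        breaks <- list(c(start, start + len - 1))
      }
      blobs <- list()
      if (v$blob_prob > 0 && stats::runif(1) < v$blob_prob) {
        br <- sample(seq(30, max(31, floor(exitr) - 30)), 1)
        bfun_top <- top * (1 - (br - 1) / exitr)
        blobs <- list(c(br, bfun_top + 12, 16,
                        0.9 - 0.45))  # lifts breast intensity to pectoral level
      }
      sp <- phantom_spec(n_rows = n_rows, n_cols = n_cols, side = side,
                         pectoral = list(present = TRUE, top_column = top,
                                         exit_row = exitr, curvature = curv),
                         noise_sd = v$noise_sd, dense_blobs = blobs,
                         edge_breaks = breaks,
                         seed = sample.int(.Machine$integer.max - 1, 1))
      ph <- if (render) generate_phantom(sp) else sp
      id <- sprintf("ph%03d_%s", k, side)
      if (render) {
        ph$image$image_id <- id
        ph$truth_pectoral$image_id <- id
        ph$truth_foreground$image_id <- id
      }
      ph$id <- id
      out[[id]] <- ph
    }
  }
  out
}
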