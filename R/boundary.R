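# Boundary extraction: reduce the 2-D edge map to a 1-D curve, one column
# position per row, following the perimeter of the bright pectoral
# candidate. Rows where the edge is broken (no edge pixel near the
# perimeter, or an implausible jump from the row above) are marked missing
# and left to the robust smoother to bridge.

#' Boundary curve container
#'
#' Per-row column position of the pectoral/breast interface. `columns` holds
#' one value per row in `row_start:row_end` (1-based, inclusive); `NA` marks
#' rows where the interface could not be observed.
#'
#' @param row_start,row_end First/last image row spanned by the interface.
#' @param columns Numeric vector of column positions (1-based, fractional
#'   allowed), `NA` for missing rows.
#' @param no_pectoral_found Flag: no usable interface in this image.
#' @export
boundary_curve <- function(row_start, row_end, columns,
                           no_pectoral_found = FALSE) {
  if (!no_pectoral_found) {
    stopifnot(row_start <= row_end,
              length(columns) == row_end - row_start + 1)
  }
  structure(list(row_start = row_start, row_end = row_end, columns = columns,
                 support_fraction = if (length(columns)) mean(!is.na(columns)) else 0,
                 no_pectoral_found = no_pectoral_found),
            class = "boundary_curve")
}

#' @export
print.boundary_curve <- function(x, ...) {
  if (x$no_pectoral_found) cat("<boundary_curve> no pectoral found\n")
  else cat(sprintf("<boundary_curve> rows %d..%d, support %.2f\n",
                   x$row_start, x$row_end, x$support_fraction))
  invisible(x)
}

dilate3x3 <- function(m) {
  out <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out | shift_mat(m, dr, dc, fill = FALSE) > 0
  }
  out
}

#' Extract the pectoral boundary from an edge map
#'
#' For every row from the top of the bright candidate down to the last row
#' where the candidate touches the chest wall (column 1), the boundary is
#' the outermost (largest-column) edge pixel lying on the candidate's
#' perimeter (within one pixel). A row is marked missing when no such pixel
#' exists or when the found column jumps more than `jump_limit` columns from
#' the previously observed row -- the signature of a dense-tissue bridge.
#'
#' @param edges An `edge_map` from [canny_edges()].
#' @param bright_candidate The candidate `binary_mask` from
#'   [binarize_bright()].
#' @param jump_limit Maximum plausible column change between consecutive
#'   observed rows, in pixels.
#' @param min_pectoral_rows Minimum number of observed rows; below this the
#'   image is declared pectoral-free.
#' @return A [boundary_curve()].
#' @export
extract_boundary <- function(edges, bright_candidate, jump_limit = 10,
                             min_pectoral_rows = 10) {
  stopifnot(inherits(edges, "edge_map"), inherits(bright_candidate, "binary_mask"))
  cand <- bright_candidate$values
  if (!any(cand)) return(boundary_curve(NA, NA, numeric(0), no_pectoral_found = TRUE))
  rows_any <- which(rowSums(cand) > 0)
  rows_wall <- which(cand[, 1])
  if (length(rows_wall) == 0)
    return(boundary_curve(NA, NA, numeric(0), no_pectoral_found = TRUE))
  row_start <- min(rows_any)
  row_end <- max(rows_wall)
  if (row_end < row_start)
    return(boundary_curve(NA, NA, numeric(0), no_pectoral_found = TRUE))

  inner <- shift_mat(cand, 1, 0, FALSE) & shift_mat(cand, -1, 0, FALSE) &
           shift_mat(cand, 0, 1, FALSE) & shift_mat(cand, 0, -1, FALSE)
  perim <- cand & !inner
  near_perim <- edges$values & dilate3x3(perim)

  cols <- rep(NA_real_, row_end - row_start + 1)
  prev <- NA_real_
  for (r in row_start:row_end) {
    hit <- which(near_perim[r, ])
    if (length(hit) == 0) next
    cc <- max(hit)
    i <- r - row_start + 1
    if (!is.na(prev) && abs(cc - prev) > jump_limit) {
      # implausible jump: leave missing, keep the previous anchor
      next
    }
    cols[i] <- cc
    prev <- cc
  }
  bc <- boundary_curve(row_start, row_end, cols)
  if (sum(!is.na(cols)) < min_pectoral_rows) bc$no_pectoral_found <- TRUE
  bc
}
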