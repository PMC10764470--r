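# Run-based connected-component labeling with union-find.
# Rows are scanned once; runs of TRUE pixels in consecutive rows are merged
# when their column intervals touch (4-connectivity: overlap; 8-connectivity:
# overlap after widening by one column).

#' Label connected components of a logical matrix
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape; 0 for background, components
#'   numbered 1..k in first-encounter (row-major) order.
#' @export
label_components <- function(mask, connectivity = 4) {
  stopifnot(is.matrix(mask), is.logical(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (!any(mask)) return(labels)

  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    invisible(NULL)
  }

  pad <- if (connectivity == 8) 1L else 0L
  prev_runs <- NULL  # matrix: start, end, id
  run_rows <- vector("list", nr)
  for (i in seq_len(nr)) {
    row <- mask[i, ]
    if (!any(row)) { prev_runs <- NULL; next }
    r <- rle(row)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    starts <- starts[keep]; ends <- ends[keep]
    ids <- length(parent) + seq_along(starts)
    parent <- c(parent, ids)
    runs <- cbind(start = starts, end = ends, id = ids)
    if (!is.null(prev_runs)) {
      # two-pointer merge over sorted, disjoint intervals
      a <- 1L; b <- 1L
      na_ <- nrow(runs); nb_ <- nrow(prev_runs)
      while (a <= na_ && b <= nb_) {
        if (runs[a, "end"] + pad < prev_runs[b, "start"]) {
          a <- a + 1L
        } else if (prev_runs[b, "end"] + pad < runs[a, "start"]) {
          b <- b + 1L
        } else {
          union2(runs[a, "id"], prev_runs[b, "id"])
          if (runs[a, "end"] < prev_runs[b, "end"]) a <- a + 1L else b <- b + 1L
        }
      }
    }
    prev_runs <- runs
    run_rows[[i]] <- runs
  }

  roots <- vapply(seq_along(parent), find, integer(1))
  relabel <- integer(length(parent))
  nxt <- 0L
  for (i in seq_along(parent)) {
    r <- roots[i]
    if (relabel[r] == 0L) { nxt <- nxt + 1L; relabel[r] <- nxt }
  }
  for (i in seq_len(nr)) {
    runs <- run_rows[[i]]
    if (is.null(runs)) next
    for (j in seq_len(nrow(runs))) {
      labels[i, runs[j, "start"]:runs[j, "end"]] <- relabel[roots[runs[j, "id"]]]
    }
  }
  labels
}

#' Largest connected component of a mask
#'
#' @inheritParams label_components
#' @return Logical matrix keeping only the largest component (ties broken by
#'   first-encounter label order); all-FALSE input returns all FALSE.
#' @export
largest_component <- function(mask, connectivity = 4) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab)
  lab == which.max(sizes)
}
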