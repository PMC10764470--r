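# Region-relative segmentation error metrics and the two comparison tests.
# FP% and FN% are both expressed relative to the TRUE pectoral area: FP% is
# the area wrongly labeled pectoral outside the true region, FN% the true
# area wrongly labeled breast. FP% can therefore exceed 100% when the
# prediction over-segments badly; FN% cannot. The per-image "mean error" is
# (FP% + FN%) / 2.

#' False-positive / false-negative percentages of a predicted mask
#'
#' @param pred Predicted pectoral `binary_mask` (or logical matrix).
#' @param truth True pectoral `binary_mask` (or logical matrix), nonempty.
#' @return Named numeric vector `c(fp_pct, fn_pct)`, both relative to the
#'   true pectoral area.
#' @export
fp_fn_percent <- function(pred, truth) {
  p <- if (inherits(pred, "binary_mask")) pred$values else pred
  t <- if (inherits(truth, "binary_mask")) truth$values else truth
  stopifnot(is.logical(p), is.logical(t))
  if (!identical(dim(p), dim(t))) stop("mask shapes differ")
  ta <- sum(t)
  if (ta == 0) stop("undefined denominator: empty truth mask")
  c(fp_pct = 100 * sum(p & !t) / ta,
    fn_pct = 100 * sum(t & !p) / ta)
}

#' Per-image mean error
#'
#' @param fp_pct,fn_pct Non-negative error percentages.
#' @return `(fp_pct + fn_pct) / 2`.
#' @export
mean_error <- function(fp_pct, fn_pct) {
  stopifnot(all(fp_pct >= 0), all(fn_pct >= 0))
  (fp_pct + fn_pct) / 2
}

#' Per-image evaluation record
#'
#' One row per evaluated image, carrying the FP/FN/mean percentages, the
#' areas, and free-form grouping labels (e.g. `method`). The identity
#' `mean_pct == (fp_pct + fn_pct) / 2` is enforced at construction.
#'
#' @param image_id Identifier.
#' @param side `"L"` or `"R"`.
#' @param fp_pct,fn_pct Error percentages from [fp_fn_percent()].
#' @param true_area,pred_area Pixel areas.
#' @param ... Additional scalar grouping labels, e.g. `method = "proposed"`.
#' @return A one-row `data.frame`.
#' @export
eval_record <- function(image_id, side, fp_pct, fn_pct,
                        true_area = NA_integer_, pred_area = NA_integer_, ...) {
  side <- match.arg(side, c("L", "R"))
  stopifnot(fp_pct >= 0, fn_pct >= 0, fn_pct <= 100)
  labels <- list(...)
  df <- data.frame(image_id = image_id, side = side,
                   fp_pct = fp_pct, fn_pct = fn_pct,
                   mean_pct = mean_error(fp_pct, fn_pct),
                   true_area = true_area, pred_area = pred_area,
                   stringsAsFactors = FALSE)
  for (nm in names(labels)) df[[nm]] <- labels[[nm]]
  df
}

#' Aggregate evaluation records into a Left/Right/Both summary
#'
#' For each value combination of the `group_by` label columns and for each
#' of Left, Right and Both (all records pooled), reports the arithmetic
#' means of FP%, FN% and mean error plus the record count -- the layout of a
#' per-method error table with FP/FN/Mean rows under Left/Right/Both
#' headings.
#'
#' @param records `data.frame` of rows built by [eval_record()].
#' @param group_by Character vector of label column names (may be empty).
#' @return Long-format `data.frame` with columns `group_by...`, `side`
#'   (`Left`/`Right`/`Both`), `metric` (`FP`/`FN`/`Mean`), `value`, `n`.
#' @export
aggregate_eval <- function(records, group_by = character(0)) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  missing_keys <- setdiff(group_by, names(records))
  if (length(missing_keys))
    stop("unknown group key(s): ", paste(missing_keys, collapse = ", "))
  grp <- if (length(group_by)) interaction(records[group_by], drop = TRUE, sep = "\r")
         else factor(rep("all", nrow(records)))
  out <- list()
  for (g in levels(grp)) {
    sub <- records[grp == g, , drop = FALSE]
    for (side in c("Left", "Right", "Both")) {
      sel <- switch(side, Left = sub$side == "L", Right = sub$side == "R",
                    Both = rep(TRUE, nrow(sub)))
      block <- sub[sel, , drop = FALSE]
      if (nrow(block) == 0) next
      vals <- c(FP = mean(block$fp_pct), FN = mean(block$fn_pct),
                Mean = mean(block$mean_pct))
      row <- data.frame(side = side, metric = names(vals), value = unname(vals),
                        n = nrow(block), stringsAsFactors = FALSE)
      if (length(group_by)) {
        keys <- strsplit(g, "\r", fixed = TRUE)[[1]]
        for (i in seq_along(group_by)) row[[group_by[i]]] <- keys[i]
        row <- row[, c(group_by, "side", "metric", "value", "n")]
      }
      out[[length(out) + 1]] <- row
    }
  }
  res <- do.call(rbind, out)
  res$side <- factor(res$side, levels = c("Left", "Right", "Both"))
  res$metric <- factor(res$metric, levels = c("FP", "FN", "Mean"))
  res <- res[order(if (length(group_by)) do.call(interaction, res[group_by]) else seq_len(nrow(res)) * 0,
                   res$side, res$metric), , drop = FALSE]
  rownames(res) <- NULL
  res$side <- as.character(res$side)
  res$metric <- as.character(res$metric)
  res
}

#' Two-sample Z test
#'
#' `z = (mean_a - mean_b) / sqrt(var_a/n_a + var_b/n_b)` with unbiased
#' sample variances and a two-sided normal p value. With zero variance in
#' both samples: equal means give `z = 0, p = 1`; unequal means give an
#' infinite `z` with `p = 0`.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List `z`, `p_two_sided`, `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
two_sample_z <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  ma <- mean(a); mb <- mean(b)
  se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
  if (se2 == 0) {
    z <- if (ma == mb) 0 else sign(ma - mb) * Inf
  } else {
    z <- (ma - mb) / sqrt(se2)
  }
  list(z = z, p_two_sided = 2 * stats::pnorm(-abs(z)),
       mean_a = ma, mean_b = mb, n_a = length(a), n_b = length(b))
}

#' Welch two-sample t test
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom and a
#' two-sided p value; degenerate zero-variance samples follow the same
#' sentinel convention as [two_sample_z()].
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List `t`, `df`, `p_two_sided`.
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    t <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    return(list(t = t, df = na + nb - 2,
                p_two_sided = if (t == 0) 1 else 0))
  }
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p_two_sided = 2 * stats::pt(-abs(t), df))
}
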