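#' Instance-averaged selection TPR and FDR
#'
#' For each instance, TPR is the fraction of truly relevant features that
#' were selected and FDR the fraction of selected features that are not
#' relevant (0 when nothing is selected); both are averaged over instances
#' and scaled to percent.
#'
#' @param masks Binary matrix, one instance per row, one feature per column
#'   (a single mask vector is accepted).
#' @param relevant Nonempty integer vector of 1-based relevant feature
#'   columns.
#' @return Named numeric vector `c(tpr_pct, fdr_pct)`.
#' @examples
#' tpr_fdr(matrix(c(1, 1, 1, 0), 1), relevant = 1:2)  # 100% TPR, 33.3% FDR
#' @export
tpr_fdr <- function(masks, relevant) {
  if (!is.matrix(masks)) masks <- matrix(masks, nrow = 1L)
  relevant <- unique(as.integer(relevant))
  if (length(relevant) == 0L) stop("relevant feature set must be nonempty")
  if (any(relevant < 1L | relevant > ncol(masks)))
    stop("relevant indices out of range")
  sel_rel <- rowSums(masks[, relevant, drop = FALSE])
  sel_all <- rowSums(masks)
  tpr <- mean(sel_rel / length(relevant))
  fdr <- mean((sel_all - sel_rel) / pmax(sel_all, 1))
  c(tpr_pct = 100 * tpr, fdr_pct = 100 * fdr)
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank statistic: the probability that a random positive
#' scores above a random negative, with ties counted one half.
#'
#' @param scores Numeric prediction scores (higher means more positive).
#' @param labels Binary labels (0/1); 1 is the positive class.
#' @return AUROC in \[0, 1\]; 0.5 for constant scores.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks: ties contribute 1/2 per pair
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-function summation `sum_k (R_k - R_{k-1}) * P_k` over the distinct
#' score thresholds taken in descending order (no trapezoidal
#' interpolation), so reported values are bit-for-bit reproducible.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1\]. Errors when no positive labels are present
#'   (recall is undefined).
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("AUPRC undefined: no positive labels")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  # block boundaries: thresholds sit at the last element of each tied block
  last_of_block <- which(s != c(s[-1L], NA) | seq_along(s) == length(s))
  tp <- cumsum(y)[last_of_block]
  k <- last_of_block  # predicted-positive count at each threshold
  precision <- tp / k
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Classification accuracy
#'
#' @param pred_labels Predicted integer labels.
#' @param labels True integer labels.
#' @return Fraction of agreeing entries.
#' @export
accuracy_score <- function(pred_labels, labels) {
  if (length(pred_labels) != length(labels)) stop("length mismatch")
  mean(pred_labels == labels)
}

#' Aggregate per-seed metric runs into a mean +/- sd report
#'
#' @param runs Data frame (or list of named vectors) with one row per seed
#'   and columns among `tpr_pct, fdr_pct, auroc, auprc, accuracy`.
#' @return A `metrics_report`: list with `mean`, `sd` (named vectors) and
#'   `n_repeats`.
#' @export
metrics_report <- function(runs) {
  if (is.list(runs) && !is.data.frame(runs))
    runs <- as.data.frame(do.call(rbind, runs))
  m <- vapply(runs, mean, numeric(1L))
  s <- if (nrow(runs) > 1L) vapply(runs, stats::sd, numeric(1L)) else
    stats::setNames(rep(0, ncol(runs)), names(runs))
  structure(list(mean = m, sd = s, n_repeats = nrow(runs)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("metrics over", x$n_repeats, "repeats (mean +/- sd):\n")
  for (k in names(x$mean))
    cat(sprintf("  %-9s %.4g +/- %.3g\n", k, x$mean[[k]], x$sd[[k]]))
  invisible(x)
}
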