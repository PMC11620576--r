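#' ROC curve, AUC, and Youden-optimal cutoff
#'
#' Sweeps every distinct score value as a threshold (a patient is called
#' positive when `score >= threshold`), collapsing ties, and records one
#' (FPR, TPR) point per threshold plus the (0, 0) corner. The AUC is the
#' trapezoidal area under the resulting step curve, which equals the
#' tie-corrected Mann-Whitney statistic U / (n1 * n0). The Youden cutoff
#' maximizes sensitivity + specificity - 1; ties are broken toward higher
#' specificity, then toward the higher threshold. Works for coarse integer
#' score grids (such as a 0--6 factor-count score) as well as continuous
#' classifier probabilities.
#'
#' @param scores Numeric vector of scores (higher = more IgAN-like).
#' @param labels Logical vector of gold-standard labels; both classes must
#'   be present.
#' @return An object of class `roc_result`: list with `thresholds`
#'   (descending), `points` (data frame `threshold`, `fpr`, `tpr`, including
#'   the (0,0) and (1,1) corners), `auc`, `youden_cutoff`, `youden_sn`,
#'   `youden_sp`.
#' @examples
#' r <- roc_curve(c(3, 2, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' r$auc
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have the same length")
  }
  if (anyNA(scores) || anyNA(labels)) stop("missing values not allowed")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("`labels` must contain at least one positive and one negative")
  }
  th <- sort(unique(scores), decreasing = TRUE)
  # counts of positives/negatives at each distinct score, accumulated from
  # the top: predicted-positive set at threshold t is {score >= t}
  pos_at <- vapply(th, function(t) sum(scores == t & labels), numeric(1))
  neg_at <- vapply(th, function(t) sum(scores == t & !labels), numeric(1))
  tpr <- cumsum(pos_at) / n1
  fpr <- cumsum(neg_at) / n0
  points <- data.frame(threshold = c(Inf, th),
                       fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (utils::head(points$tpr, -1) +
                                   utils::tail(points$tpr, -1)) / 2)
  j <- tpr - fpr
  # near-ties (within rounding of the ratio arithmetic) count as exact ties
  best <- which(j >= max(j) - 1e-12)
  if (length(best) > 1L) best <- best[order(fpr[best], -th[best])][1L]
  structure(
    list(thresholds = th, points = points, auc = auc,
         youden_cutoff = th[best], youden_sn = tpr[best],
         youden_sp = 1 - fpr[best]),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC %.4f over %d thresholds>\n",
              x$auc, length(x$thresholds)))
  cat(sprintf("  Youden cutoff >= %g: Sn %.4f, Sp %.4f\n",
              x$youden_cutoff, x$youden_sn, x$youden_sp))
  invisible(x)
}

#' Mean and sample standard deviation of fold AUCs
#'
#' Summarizes per-fold AUCs as mean +/- SD, with the sample (n - 1)
#' standard deviation.
#'
#' @param aucs Numeric vector of length >= 2.
#' @return List with `mean` and `sd`.
#' @export
auc_mean_sd <- function(aucs) {
  if (length(aucs) < 2L) stop("need at least 2 AUC values")
  list(mean = mean(aucs), sd = stats::sd(aucs))
}

#' Export ROC points as a CSV file
#'
#' @param roc A `roc_result`.
#' @param path Output path; columns `threshold`, `fpr`, `tpr`.
#' @return Invisibly, `roc`.
#' @export
write_roc_csv <- function(roc, path) {
  stopifnot(inherits(roc, "roc_result"))
  write_csv_lf(roc$points, path)
  invisible(roc)
}
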