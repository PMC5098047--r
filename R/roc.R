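# ROC / AUC machinery: rank-statistic AUC, threshold-sweep curves, and the
# paired chi-square AUC comparison built on DeLong placement covariances.

#' ROC curve and AUC
#'
#' AUC is computed as the rank statistic: the probability that a random
#' positive outscores a random negative, ties counting one half. The curve
#' is a threshold sweep over the distinct scores (thresholds applied as
#' `score >= t`), from (0, 0) to (1, 1).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical or 0/1 labels; both classes must be present.
#' @return A `roc_result`: list with `fpr`, `tpr`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(labels & scores >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(!labels & scores >= t), numeric(1))
  structure(list(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

# DeLong placement values: for each positive, the fraction of negatives it
# outscores (+ half ties); and symmetrically for negatives.
delong_placements <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)),
                numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)),
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Paired chi-square comparison of two AUCs
#'
#' Both score vectors must be computed on the identical samples. The
#' statistic is `(AUC_a - AUC_b)^2 / Var(AUC_a - AUC_b)` with the variance
#' of the difference from the paired DeLong placement covariances, referred
#' to a chi-square distribution with 1 degree of freedom.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Common labels.
#' @return List `statistic`, `df`, `p.value`, `auc_a`, `auc_b`.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop("compare_auc requires paired scores on identical samples")
  }
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  stat <- if (var_diff <= .Machine$double.eps) {
    if (abs(d) < 1e-12) 0 else Inf
  } else d^2 / var_diff
  list(statistic = stat, df = 1L,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       auc_a = pa$auc, auc_b = pb$auc)
}

#' AUC of each model across PTM-count thresholds
#'
#' For threshold `t`, the scored set is restricted to MAPs with
#' `1 <= ptm_count <= t` and each model's AUC recomputed on the
#' restriction. Rows where a class vanishes are `NA`.
#'
#' @param scores Named list of score vectors (one per model), all aligned
#'   with `labels` and `ptm_count`.
#' @param labels Known-function labels.
#' @param ptm_count PTM count per MAP.
#' @param thresholds Integer thresholds (default 1:10).
#' @return data.frame `threshold`, `n`, one AUC column per model.
#' @export
auc_vs_ptm_count_threshold <- function(scores, labels, ptm_count,
                                       thresholds = 1:10) {
  labels <- as.logical(labels)
  out <- data.frame(threshold = thresholds,
                    n = vapply(thresholds, function(t) sum(ptm_count <= t),
                               numeric(1)))
  for (nm in names(scores)) {
    out[[nm]] <- vapply(thresholds, function(t) {
      keep <- ptm_count <= t
      if (!any(labels[keep]) || all(labels[keep])) return(NA_real_)
      roc_auc(scores[[nm]][keep], labels[keep])$auc
    }, numeric(1))
  }
  out
}

#' AUC stratified by known-function source-count bin
#'
#' For each bin, the positives are the known-function MAPs of that bin and
#' the negatives are all unknown-function MAPs; empty bins give `NA`.
#'
#' @param scores Score vector.
#' @param labels Known-function labels.
#' @param kfsc_bins Bin per MAP (as from [kfsc_bin()]).
#' @param bins Bin order for the output.
#' @return data.frame `bin`, `n_pos`, `auc`.
#' @export
auc_by_kfsc <- function(scores, labels, kfsc_bins,
                        bins = c("1", "2", "3", "4", "5-10", "11+")) {
  labels <- as.logical(labels)
  neg <- which(!labels)
  rows <- lapply(bins, function(b) {
    pos <- which(labels & kfsc_bins == b)
    auc <- if (length(pos) && length(neg)) {
      idx <- c(pos, neg)
      roc_auc(scores[idx], c(rep(TRUE, length(pos)),
                             rep(FALSE, length(neg))))$auc
    } else NA_real_
    data.frame(bin = b, n_pos = length(pos), auc = auc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
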