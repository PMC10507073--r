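#' Aggregate per-chunk note scores into one patient probability
#'
#' Combines the chunk-level readmission probabilities of one patient's
#' note as `(P_max + P_mean * n/2) / (1 + n/2)`, where `P_max` and
#' `P_mean` are the maximum and arithmetic mean over the `n` chunks.
#' The result always lies between `P_mean` and `P_max`; with a single
#' chunk it collapses to that chunk's probability.
#'
#' @param scores numeric vector of chunk probabilities in `[0, 1]`.
#' @return aggregated probability.
#' @export
aggregateChunkScores <- function(scores) {
  n <- length(scores)
  if (n < 1L) stop("empty chunk scores")
  if (any(scores < 0 | scores > 1)) stop("chunk scores must lie in [0, 1]")
  (max(scores) + mean(scores) * n / 2) / (1 + n / 2)
}

.f1At <- function(scores, labels, threshold) {
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Threshold maximizing F1
#'
#' Scans the candidate thresholds implied by the observed scores —
#' midpoints between consecutive distinct scores, plus the minimum
#' score (all-positive) — and returns the one maximizing F1, preferring
#' the lowest on ties. Intended to be computed on validation
#' predictions and then applied to the test set.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes present).
#' @return the selected threshold.
#' @export
findOptimalThreshold <- function(scores, labels) {
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  s <- sort(unique(scores))
  candidates <- if (length(s) > 1L)
    sort(c(s[1], (s[-length(s)] + s[-1]) / 2)) else s
  f1s <- vapply(candidates, function(th) .f1At(scores, labels, th)["f1"],
                numeric(1))
  candidates[which.max(f1s)]  # which.max takes the first (lowest) on ties
}

#' Compute the five-metric report for one set of predictions
#'
#' AUROC is the concordance probability over positive-negative pairs
#' with ties counted one half; AUPRC is the step-wise integral of
#' precision over recall across score thresholds; precision, recall and
#' F1 are taken at the given threshold (`score >= threshold` predicts
#' positive).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (both classes present).
#' @param threshold decision threshold for the thresholded metrics.
#' @param fold optional fold identifier carried into the report.
#' @return one-row `data.table`: `fold`, `auroc`, `f1`, `auprc`,
#'   `precision`, `recall`, `threshold`.
#' @export
computeMetrics <- function(scores, labels, threshold = 0.5, fold = NA) {
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)

  ord <- order(scores, decreasing = TRUE)
  lab_sorted <- labels[ord]; s_sorted <- scores[ord]
  # evaluate precision/recall at each distinct-score cut (ties grouped)
  is_last_of_group <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  tp <- cumsum(lab_sorted)[is_last_of_group]
  npred <- seq_along(lab_sorted)[is_last_of_group]
  prec <- tp / npred
  rec <- tp / npos
  auprc <- sum(diff(c(0, rec)) * prec)

  thr <- .f1At(scores, labels, threshold)
  data.table::data.table(
    fold = fold, auroc = auroc, f1 = unname(thr["f1"]), auprc = auprc,
    precision = unname(thr["precision"]), recall = unname(thr["recall"]),
    threshold = threshold)
}

.metricNames <- function() c("auroc", "f1", "auprc", "precision", "recall")

#' Is one model conclusively better than another?
#'
#' A model is conclusively better than another if it scores strictly
#' higher on at least three of the five metrics (AUROC, F1, AUPRC,
#' precision, recall), compared at the same fold-aggregation level.
#'
#' @param a,b metric reports (one row each, or named vectors).
#' @return logical.
#' @export
conclusivelyBetter <- function(a, b) {
  wins <- vapply(.metricNames(), function(m)
    as.numeric(a[[m]]) > as.numeric(b[[m]]), logical(1))
  sum(wins) >= 3L
}

#' Aggregate metric reports across folds
#'
#' Per-metric sample mean and sample (n-1) standard deviation, with a
#' `mean ± std` rendering to 4 decimals.
#'
#' @param reports `data.table` of per-fold reports ([computeMetrics()]).
#' @return `data.table` of `metric`, `mean`, `sd`, `formatted`.
#' @export
aggregateFolds <- function(reports) {
  if (nrow(reports) < 2L) stop("need at least 2 fold reports")
  data.table::rbindlist(lapply(.metricNames(), function(m) {
    v <- as.numeric(reports[[m]])
    data.table::data.table(
      metric = m, mean = mean(v), sd = sd(v),
      formatted = sprintf("%.4f ± %.4f", mean(v), sd(v)))
  }))
}
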