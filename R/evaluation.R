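#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) identity: the probability that a
#' uniformly chosen positive outranks a uniformly chosen negative, with
#' ties counted one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  check_binary(labels, scores)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUROC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Interpolation-free step summation: scores are processed in decreasing
#' order, tied scores as one group, and the area is
#' `sum_k (R_k - R_{k-1}) * P_k` over the distinct thresholds.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1\].
#' @export
auprc <- function(scores, labels) {
  check_binary(labels, scores)
  n1 <- sum(labels == 1)
  if (n1 == 0) stop("AUPRC undefined: no positive labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- rowsum(as.numeric(y), grp)[, 1]
  n_g <- rowsum(rep(1, length(y)), grp)[, 1]
  tp <- cumsum(tp_g); np <- cumsum(n_g)
  prec <- tp / np
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' F1 score at a fixed probability threshold
#'
#' Predictions are `scores >= threshold`. Returns 0 when there are no
#' predicted positives or no true positives (the usual convention).
#'
#' @inheritParams auroc
#' @param threshold Classification threshold (default 0.5).
#' @return F1 in \[0, 1\].
#' @export
f1_at_threshold <- function(scores, labels, threshold = 0.5) {
  check_binary(labels, scores)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

check_binary <- function(labels, scores) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (length(labels) == 0) stop("empty input")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (any(!is.finite(scores))) stop("scores must be finite")
  invisible(TRUE)
}

#' All three classification metrics at once
#' @inheritParams f1_at_threshold
#' @return Named numeric vector `f1`, `auroc`, `auprc`.
#' @export
run_metrics <- function(scores, labels, threshold = 0.5) {
  c(f1 = f1_at_threshold(scores, labels, threshold),
    auroc = auroc(scores, labels),
    auprc = auprc(scores, labels))
}

#' Student-t confidence interval for a mean
#'
#' `mean +/- t_{(1+level)/2, n-1} * sd / sqrt(n)` with the sample
#' standard deviation (n - 1 denominator).
#'
#' @param values Numeric vector, length >= 2.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lo, hi)`.
#' @export
t_confidence_interval <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a t interval")
  m <- mean(values)
  half <- stats::qt((1 + level) / 2, df = n - 1) * stats::sd(values) / sqrt(n)
  c(lo = m - half, hi = m + half)
}

# Welch two-sample t-test p-value with a zero-variance convention:
# if both vectors are constant, p = 1 when the means agree and 0 otherwise.
welch_pvalue <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  tryCatch(stats::t.test(x, y, var.equal = FALSE)$p.value,
           error = function(e) {
             if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
           })
}

#' Pairwise t-test p-value matrix across models
#'
#' Entry (i, j) is the two-sample (Welch) t-test p-value comparing model
#' i's and model j's per-run AUROC vectors. The matrix is symmetric with
#' unit diagonal.
#'
#' @param run_vectors Named list of equal-length numeric vectors (one
#'   AUROC per run per model).
#' @return Symmetric numeric matrix with the models' names.
#' @export
pvalue_matrix <- function(run_vectors) {
  k <- length(run_vectors)
  if (k < 1) stop("need at least one model")
  lens <- lengths(run_vectors)
  if (length(unique(lens)) != 1) stop("all models need the same run count")
  nm <- names(run_vectors)
  if (is.null(nm)) nm <- paste0("model", seq_len(k))
  out <- diag(1, k)
  dimnames(out) <- list(nm, nm)
  if (k >= 2) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        p <- welch_pvalue(run_vectors[[i]], run_vectors[[j]])
        out[i, j] <- p; out[j, i] <- p
      }
    }
  }
  out
}
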