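#' Area under the ROC curve
#'
#' Rank-based AUC: the proportion of (positive, negative) score pairs ranked
#' concordantly, counting ties as one half,
#' \eqn{AUC = (C + 0.5 T)/(n_1 n_0)}. Computed via the Mann-Whitney rank-sum
#' identity, which is exactly equivalent to pair counting.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 class labels (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
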