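#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimate: the probability that a randomly
#' chosen presence is scored above a randomly chosen absence, ties counting
#' one half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels (1 = presence).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: both classes required")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic with threshold optimisation
#'
#' Scans a fixed threshold grid (default 101 points on `[0, 1]`); a record
#' is predicted present when its score is `>=` the threshold. Returns the
#' maximum of sensitivity + specificity - 1 and the threshold attaining it
#' (the smallest such threshold on ties).
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels.
#' @param thresholds threshold grid (default `seq(0, 1, length.out = 101)`).
#' @return list with `tss`, `threshold`, `sensitivity`, `specificity`.
#' @export
tss_score <- function(scores, labels, thresholds = seq(0, 1, length.out = 101)) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("TSS undefined: both classes required")
  sens <- spec <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    pred <- scores >= thresholds[k]
    sens[k] <- sum(pred & labels == 1) / n1
    spec[k] <- sum(!pred & labels == 0) / n0
  }
  tss <- sens + spec - 1
  best <- which.max(tss)  # first index = smallest threshold on ties
  list(tss = tss[best], threshold = thresholds[best],
       sensitivity = sens[best], specificity = spec[best])
}
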