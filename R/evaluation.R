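#' ROC curve for case-vs-control scores
#'
#' Standard ROC over the unique score values, tied scores grouped into a
#' single threshold step (so all-equal scores give exactly the diagonal).
#' The positive class is case (label 1) and the orientation is never
#' auto-flipped: a classifier worse than chance reports an AUC below 0.5.
#'
#' @param scores Numeric vector of per-sample scores (higher = more
#'   case-like).
#' @param labels Binary 0/1 vector (1 = case).
#' @return A `roc_result`: `thresholds` (descending, starting `Inf`), `fpr`
#'   and `tpr` (nondecreasing, from (0,0) to (1,1)), and `auc` (trapezoidal
#'   area of the stored curve).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  n_case <- sum(labels == 1L)
  n_ctrl <- sum(labels == 0L)
  if (n_case == 0L || n_ctrl == 0L)
    stop("degenerate labels: both classes must be present", call. = FALSE)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp_end <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(1L - l)[grp_end]
  thresholds <- c(Inf, s[grp_end])
  tpr <- c(0, tp / n_case)
  fpr <- c(0, fp / n_ctrl)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(thresholds = thresholds, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_result")
}

#' Area under the ROC curve
#'
#' Trapezoidal integral of [roc_curve()]; algebraically equal to the
#' Mann-Whitney statistic (fraction of case/control pairs correctly
#' ordered, ties counted one half).
#'
#' @inheritParams roc_curve
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) roc_curve(scores, labels)$auc

#' Classification accuracy
#'
#' @param predicted,truth Equal-length label vectors.
#' @return Fraction of positions where they agree.
#' @export
accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth differ in length", call. = FALSE)
  mean(predicted == truth)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: %d threshold steps, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}
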