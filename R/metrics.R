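# coerce labels to a logical soluble indicator; soluble is the positive class
.as_soluble <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (!all(labels %in% c("soluble", "insoluble"))) {
    .stop_input("labels must be 'soluble'/'insoluble' or logical")
  }
  labels == "soluble"
}

#' Area under the ROC curve (rank-based, tie-corrected)
#'
#' Computed from the Mann-Whitney statistic: the probability that a randomly
#' chosen soluble sequence scores strictly above a randomly chosen insoluble
#' one, counting ties as one half. Exact under ties; no threshold grid.
#'
#' @param scores numeric scores ("higher means more soluble").
#' @param labels matching labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  sol <- .as_soluble(labels)
  if (length(scores) != length(sol)) .stop_input("scores and labels differ in length")
  n1 <- sum(sol); n0 <- sum(!sol)
  if (n1 == 0L || n0 == 0L) .stop_input("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[sol]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Accuracy, sensitivity and specificity of a labeling
#'
#' Soluble is the positive class: sensitivity is the fraction of soluble
#' sequences called soluble, specificity the fraction of insoluble sequences
#' called insoluble. With a single-class truth the undefined rate is `NaN`.
#'
#' @param predictions predicted labels.
#' @param labels true labels.
#' @return named numeric: accuracy, sensitivity, specificity.
#' @export
confusion_metrics <- function(predictions, labels) {
  if (length(predictions) != length(labels)) .stop_input("length mismatch")
  if (length(labels) == 0L) .stop_input("empty input")
  pred <- .as_soluble(predictions)
  truth <- .as_soluble(labels)
  c(accuracy = mean(pred == truth),
    sensitivity = sum(pred & truth) / sum(truth),
    specificity = sum(!pred & !truth) / sum(!truth))
}

#' Pearson product-moment correlation of two 20-residue score vectors
#'
#' @param x,y numeric vectors of equal length with nonzero variance.
#' @return correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) .stop_input("vectors differ in length")
  if (anyNA(x) || anyNA(y)) .stop_input("missing values not allowed")
  if (sd(x) == 0 || sd(y) == 0) .stop_degenerate("zero-variance input to pearson_r")
  cor(x, y)
}

#' Bundle the quantities entering the optimizer's fitness
#'
#' One row of the run-summary table: the weighted fitness, the cross-validated
#' AUC, the amino-acid conservation correlation R, training (and optionally
#' test) accuracy, sensitivity, specificity and the selected threshold.
#'
#' @param auc cross-validated AUC.
#' @param r conservation correlation against the initial amino-acid scores.
#' @param w1,w2 fitness weights.
#' @param train_accuracy,test_accuracy,sensitivity,specificity,threshold
#'   remaining summary columns (test accuracy may be `NA`).
#' @return object of class `fitness_result`.
#' @export
fitness_result <- function(auc, r, w1, w2, train_accuracy, sensitivity,
                           specificity, threshold, test_accuracy = NA_real_) {
  structure(list(auc = auc, r = r, fitness = w1 * auc + w2 * r,
                 train_accuracy = train_accuracy, test_accuracy = test_accuracy,
                 sensitivity = sensitivity, specificity = specificity,
                 threshold = threshold, w1 = w1, w2 = w2),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf("fitness %.4f = %.2g x AUC %.4f + %.2g x R %.4f | train acc %.4f, threshold %.2f\n",
              x$fitness, x$w1, x$auc, x$w2, x$r, x$train_accuracy, x$threshold))
  invisible(x)
}

#' @export
as.data.frame.fitness_result <- function(x, ...) {
  data.frame(fitness = x$fitness, train_pct = 100 * x$train_accuracy,
             test_pct = 100 * x$test_accuracy, sensitivity = x$sensitivity,
             specificity = x$specificity, auc = x$auc, r = x$r,
             threshold = x$threshold)
}
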