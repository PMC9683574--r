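#' Test accuracy
#'
#' Fraction of exact label matches, the classification inference measure
#' conventional for fixed train/test benchmark splits.
#'
#' @param predicted,truth label vectors of equal length.
#' @return A scalar in `[0, 1]`.
#' @export
test_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) < 1L)
    stop("predicted and truth must be equal-length, non-empty vectors",
         call. = FALSE)
  mean(predicted == truth)
}

#' Mean per-class error
#'
#' Default (`per_instance = FALSE`): the per-class error rates `err_c` are
#' computed from the confusion of each class and averaged over the classes
#' present in `truth`, `MPCE = mean(err_c)` — the class-balance-aware
#' complement of accuracy (for balanced classes it equals `1 - accuracy`
#' exactly). The alternative `per_instance = TRUE` weighting averages each
#' instance's class error rate over instances. Classes declared but absent
#' from `truth` are excluded with a warning and the denominator adjusted.
#'
#' @param predicted,truth label vectors with `truth` values in `1..n_classes`
#'   (or any common coding; classes are taken from `1..n_classes`).
#' @param n_classes number of classes C (>= 2).
#' @param per_instance use the per-instance weighting instead of the
#'   per-class mean.
#' @return A non-negative scalar; 0 iff every class error is 0.
#' @export
mpce <- function(predicted, truth, n_classes, per_instance = FALSE) {
  if (length(predicted) != length(truth) || length(truth) < 1L)
    stop("predicted and truth must be equal-length, non-empty vectors",
         call. = FALSE)
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  classes <- seq_len(n_classes)
  if (!all(truth %in% classes))
    stop("truth labels outside 1..n_classes", call. = FALSE)
  present <- classes[classes %in% truth]
  if (length(present) < n_classes)
    warning("classes absent from truth are excluded from MPCE: ",
            paste(setdiff(classes, present), collapse = ","), call. = FALSE)
  err <- vapply(present, function(c) mean(predicted[truth == c] != c),
                numeric(1))
  if (per_instance) {
    err_by_class <- setNames(err, present)
    return(mean(err_by_class[as.character(truth)]))
  }
  mean(err)
}

#' Relative learning gain over a base model
#'
#' `(acc - acc_base) / acc_base`: the relative test-accuracy improvement of
#' the full pipeline over the plain base fit.
#'
#' @param acc_shapaal,acc_base accuracies; `acc_base` must be positive.
#' @return Signed relative gain, 0 when equal.
#' @export
learning_gain <- function(acc_shapaal, acc_base) {
  if (!is.finite(acc_base) || acc_base <= 0)
    stop("learning gain is undefined for acc_base <= 0", call. = FALSE)
  (acc_shapaal - acc_base) / acc_base
}

#' Training insufficiency factor
#'
#' Ratio of training to testing instances; values below 1 mark the
#' scarce-training regime the method addresses.
#'
#' @param n_train,n_test positive instance counts.
#' @return `n_train / n_test` as a real.
#' @export
insufficiency_factor <- function(n_train, n_test) {
  if (n_train < 1 || n_test < 1)
    stop("both counts must be >= 1", call. = FALSE)
  n_train / n_test
}

#' Differential gain over a reported benchmark
#'
#' `(acc - benchmark) / benchmark`; positive means the benchmark is
#' outperformed. Vectorized over pairs.
#'
#' @param acc achieved accuracy (or vector).
#' @param benchmark reported benchmark accuracy (or vector), must be > 0.
#' @return Signed relative difference(s).
#' @export
differential_gain <- function(acc, benchmark) {
  if (any(!is.finite(benchmark)) || any(benchmark <= 0))
    stop("benchmark must be positive", call. = FALSE)
  (acc - benchmark) / benchmark
}

#' Mode of per-seed accuracies
#'
#' Neural-network training is run under many seeds and the reported result is
#' the most frequent (mode) of the obtained test accuracies, after rounding
#' to the reporting precision. Count ties break toward the larger value.
#'
#' @param per_seed_accuracies numeric vector (>= 1 entries).
#' @param rounding decimal places before counting (default 4, the reporting
#'   precision).
#' @return The modal accuracy.
#' @export
mode_accuracy <- function(per_seed_accuracies, rounding = 4L) {
  if (length(per_seed_accuracies) < 1L)
    stop("need at least one accuracy", call. = FALSE)
  x <- round(per_seed_accuracies, rounding)
  tab <- table(x)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  max(cand)
}
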