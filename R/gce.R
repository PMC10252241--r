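#' Loss batch container
#'
#' Bundles predicted class probabilities with true labels plus the epoch
#' bookkeeping needed by the gradual cross-entropy: `epoch_size` (N, examples
#' allocated to the epoch) and `consumed` (l, examples actually processed
#' before an early abort). The probability rows must each sum to 1 and the
#' number of rows must equal `consumed`.
#'
#' @param probs numeric matrix, one row per consumed example, one column per
#'   class; rows sum to 1 (tolerance 1e-6).
#' @param labels true classes: integer indices in `1..C`, or a one-hot matrix
#'   (converted to indices).
#' @param epoch_size N, total examples allocated to the epoch.
#' @param consumed l, examples processed (defaults to `nrow(probs)`).
#' @return object of class `loss_batch`.
#' @export
loss_batch <- function(probs, labels, epoch_size = nrow(probs),
                       consumed = nrow(probs)) {
  probs <- as.matrix(probs)
  if (is.matrix(labels)) {
    if (!all(dim(labels) == dim(probs))) {
      stop("one-hot labels must match probs dimensions")
    }
    labels <- max.col(labels, ties.method = "first")
  }
  labels <- as.integer(labels)
  if (any(labels < 1L | labels > ncol(probs))) {
    stop("labels out of range 1..C")
  }
  if (length(labels) != nrow(probs)) stop("one label per probability row")
  if (any(probs < 0)) stop("probabilities must be nonnegative")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("each probability row must sum to 1 (tolerance 1e-6)")
  }
  if (consumed < 1L || consumed > epoch_size) {
    stop("consumed must satisfy 1 <= l <= N")
  }
  if (nrow(probs) != consumed) {
    stop("number of prob/label pairs must equal consumed")
  }
  structure(list(probs = probs, labels = labels,
                 epoch_size = as.integer(epoch_size),
                 consumed = as.integer(consumed)),
            class = "loss_batch")
}

#' Gradual weighting coefficient
#'
#' \eqn{\delta = N / l}: the factor that rescales an epoch's summed
#' cross-entropy when only `l` of the `N` allocated examples were consumed
#' before the epoch was aborted.
#'
#' @param epoch_size N, examples allocated to the epoch.
#' @param consumed l, examples consumed, `1 <= l <= N`.
#' @return `N / l` exactly.
#' @export
#' @examples
#' delta_coefficient(100, 50)  # 2
delta_coefficient <- function(epoch_size, consumed) {
  if (length(epoch_size) != 1L || length(consumed) != 1L ||
      !is.finite(epoch_size) || !is.finite(consumed)) {
    stop("epoch_size and consumed must be finite scalars")
  }
  if (consumed < 1 || consumed > epoch_size) {
    stop("delta_coefficient(): need 1 <= consumed <= epoch_size")
  }
  epoch_size / consumed
}

# p_true clamped at this floor before log(); keeps the loss finite for
# degenerate zero-probability predictions
.CE_PROB_FLOOR <- 1e-12

per_example_ce <- function(batch) {
  p_true <- batch$probs[cbind(seq_along(batch$labels), batch$labels)]
  -log(pmax(p_true, .CE_PROB_FLOOR))
}

#' Categorical cross-entropy over a full epoch
#'
#' \eqn{J(w) = -\frac{1}{N}\sum_{i=1}^{N} \log p_{model}(y_i)}: the mean
#' negative log-probability of the true class. Requires the batch to cover
#' the full epoch (`consumed == epoch_size`); use [gce()] for aborted epochs.
#' True-class probabilities are clamped at 1e-12 so the result is always
#' finite.
#'
#' @param batch a [loss_batch] with `consumed == epoch_size`.
#' @return nonnegative scalar loss.
#' @export
cross_entropy <- function(batch) {
  stopifnot(inherits(batch, "loss_batch"))
  if (batch$consumed != batch$epoch_size) {
    stop("cross_entropy() requires a fully consumed epoch; use gce()")
  }
  mean(per_example_ce(batch))
}

#' Gradual cross-entropy
#'
#' Cross-entropy of an epoch that may have been aborted early:
#' \eqn{J(w) = -\frac{\delta}{N}\sum_{i=1}^{l} \log p_{model}(y_i)} with
#' \eqn{\delta = N/l}, which algebraically equals the mean cross-entropy over
#' the `l` consumed examples. The discarded remainder of the epoch therefore
#' neither dilutes nor inflates the loss estimate. With `l == N` this reduces
#' to [cross_entropy()].
#'
#' @param batch a [loss_batch].
#' @return nonnegative scalar loss.
#' @export
gce <- function(batch) {
  stopifnot(inherits(batch, "loss_batch"))
  delta <- delta_coefficient(batch$epoch_size, batch$consumed)
  (delta / batch$epoch_size) * sum(per_example_ce(batch))
}
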