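#' Adaptive patience state
#'
#' Running statistics over a monitored measure (here: validation loss) that
#' drive the adaptive early-stopping decision. The threshold is not a fixed
#' epoch count but the running average of the successive differences
#' \eqn{\epsilon_i = t_i - t_{i-1}} of the monitored values: an observation
#' counts as a stall when its difference fails to beat that running average,
#' i.e. when the model is no longer improving faster than its own history.
#'
#' Two threshold modes are provided. The default, `"incremental"`, maintains
#' the exact arithmetic mean of all differences seen so far via the standard
#' incremental update \eqn{A_k = A_{k-1} + (\epsilon_k - A_{k-1})/k}. The
#' `"literal"` mode instead uses \eqn{(A_{k-1} + \epsilon_k)/(i+1)} with
#' \eqn{i} the observation index, which divides a sum of two terms by the
#' observation count; it is retained for comparison but is not a running mean.
#' In both modes the `running_avg_diff` field is the true arithmetic mean of
#' the differences (an invariant tested against a brute-force oracle); only
#' `patience_threshold` differs.
#'
#' @param mode threshold update rule, `"incremental"` (default) or `"literal"`.
#' @return an object of class `patience_state` with fields `step_index`
#'   (observations so far), `last_value`, `running_avg_diff`,
#'   `patience_threshold` (`NA` until two differences exist), `stall_count`,
#'   `n_diffs`, and `mode`.
#' @seealso [observe()], [should_stop_macro()], [should_stop_micro()]
#' @export
#' @examples
#' st <- init_patience()
#' st <- observe(st, 1.0)
#' st <- observe(st, 0.8)
#' st$running_avg_diff  # -0.2
init_patience <- function(mode = c("incremental", "literal")) {
  mode <- match.arg(mode)
  structure(
    list(
      step_index = 0L,
      last_value = NA_real_,
      running_avg_diff = NA_real_,
      patience_threshold = NA_real_,
      stall_count = 0L,
      n_diffs = 0L,
      mode = mode
    ),
    class = "patience_state"
  )
}

#' Record one monitored observation
#'
#' Feeds the next value of the monitored measure (validation loss) into the
#' patience state. From the second observation on, the difference
#' \eqn{\epsilon = t_i - t_{i-1}} is formed; it is compared against the
#' threshold as it stood *before* this observation (a difference strictly
#' below the current threshold is an improvement and resets the stall count;
#' \eqn{\epsilon \ge} threshold increments it), and then folded into the
#' running average which becomes the new threshold. No stall can be scored
#' before two differences exist, so a stop is impossible with fewer than
#' three observations.
#'
#' @param state a [`patience_state`][init_patience].
#' @param value finite numeric scalar, the new monitored value.
#' @return the updated `patience_state`.
#' @export
observe <- function(state, value) {
  stopifnot(inherits(state, "patience_state"))
  if (length(value) != 1L || !is.numeric(value) || !is.finite(value)) {
    stop("observe(): monitored value must be a finite numeric scalar")
  }
  value <- as.numeric(value)
  state$step_index <- state$step_index + 1L
  if (is.na(state$last_value)) {
    state$last_value <- value
    return(state)
  }
  eps <- value - state$last_value
  # stall is judged against the threshold at the time eps is observed,
  # which requires at least one earlier difference
  if (state$n_diffs >= 1L) {
    if (eps >= state$patience_threshold) {
      state$stall_count <- state$stall_count + 1L
    } else {
      state$stall_count <- 0L
    }
  }
  k <- state$n_diffs + 1L
  prev_avg <- if (k == 1L) 0 else state$running_avg_diff
  new_avg <- prev_avg + (eps - prev_avg) / k
  state$patience_threshold <- if (state$mode == "incremental") {
    new_avg
  } else {
    # literal printed form: (avg of previous diffs + current diff)/(i + 1)
    (prev_avg + eps) / (state$step_index + 1L)
  }
  state$running_avg_diff <- new_avg
  state$n_diffs <- k
  state$last_value <- value
  state
}

stop_decision <- function(stop, level, reason) {
  stopifnot(is.logical(stop), level %in% c("macro", "micro", "none"))
  if (!stop && level != "none") stop("non-stop decision must have level 'none'")
  if (stop && level == "none") stop("stop decision must carry a level")
  structure(list(stop = stop, level = level, reason = reason),
            class = "stop_decision")
}

#' @export
print.stop_decision <- function(x, ...) {
  cat(sprintf("<stop_decision> stop=%s level=%s  %s\n", x$stop, x$level, x$reason))
  invisible(x)
}

#' Epoch-level (macro) stopping decision
#'
#' The macro controller aborts the whole training run once `window`
#' consecutive epoch-level observations have failed to improve beyond the
#' adaptive threshold, provided more than `min_epochs` observations have been
#' made (a warm-up guard against immature early stopping).
#'
#' @param state a [`patience_state`][init_patience] fed with per-epoch
#'   validation losses.
#' @param window number of consecutive stalled evaluations that trigger the
#'   stop (>= 1).
#' @param min_epochs observations required before a stop is permitted.
#' @return a `stop_decision` with fields `stop`, `level` (`"macro"` or
#'   `"none"`) and `reason`.
#' @export
should_stop_macro <- function(state, window = 3L, min_epochs = 3L) {
  stopifnot(inherits(state, "patience_state"))
  if (length(window) != 1L || !is.numeric(window) || window < 1) {
    stop("should_stop_macro(): window must be >= 1")
  }
  if (state$step_index > min_epochs && state$stall_count >= window) {
    return(stop_decision(TRUE, "macro", sprintf(
      "no improvement beyond adaptive threshold for %d epoch evaluations",
      state$stall_count
    )))
  }
  stop_decision(FALSE, "none", "improving or within warm-up")
}

#' Batch-level (micro) stopping decision
#'
#' The micro controller applies the same stall rule to within-epoch
#' (batch-cadence) validation checks, but a micro stop aborts only the
#' current epoch; training resumes with the next one. There is no warm-up
#' guard at this level.
#'
#' @inheritParams should_stop_macro
#' @return a `stop_decision` with `level` `"micro"` or `"none"`.
#' @export
should_stop_micro <- function(state, window = 3L) {
  stopifnot(inherits(state, "patience_state"))
  if (length(window) != 1L || !is.numeric(window) || window < 1) {
    stop("should_stop_micro(): window must be >= 1")
  }
  if (state$stall_count >= window) {
    return(stop_decision(TRUE, "micro", sprintf(
      "no improvement beyond adaptive threshold for %d in-epoch evaluations",
      state$stall_count
    )))
  }
  stop_decision(FALSE, "none", "improving within epoch")
}

#' @export
print.patience_state <- function(x, ...) {
  cat(sprintf(
    "<patience_state> mode=%s  i=%d  last=%.6g  avg_diff=%.6g  threshold=%.6g  stalls=%d\n",
    x$mode, x$step_index, x$last_value, x$running_avg_diff,
    x$patience_threshold, x$stall_count
  ))
  invisible(x)
}
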