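# Rate <-> probability conversions used throughout the model.
# Transition inputs reported as rates or multi-year risks are converted to
# annual probabilities through these functions only; nothing else guesses.

#' Convert an event rate to a transition probability
#'
#' Under a constant hazard, the probability that at least one event occurs in
#' `time` years is `1 - exp(-rate * time)`.
#'
#' @param rate Non-negative event rate, per year.
#' @param time Length of the interval in years (default one model cycle).
#' @return Probability in `[0, 1)`. Vectorised over both arguments.
#' @examples
#' rate_to_probability(0.10536052, 1) # ~0.1
#' @seealso [probability_to_rate()] for the inverse.
#' @export
rate_to_probability <- function(rate, time = 1) {
  if (!is.numeric(rate) || !is.numeric(time)) {
    stop("`rate` and `time` must be numeric", call. = FALSE)
  }
  if (any(rate < 0)) stop("`rate` must be non-negative", call. = FALSE)
  if (any(time <= 0)) stop("`time` must be positive", call. = FALSE)
  1 - exp(-rate * time)
}

#' Convert a transition probability to the underlying constant rate
#'
#' Inverse of [rate_to_probability()]: `-log(1 - p) / time`.
#'
#' @param p Probability in `[0, 1)`.
#' @param time Length of the interval in years.
#' @return Event rate per year.
#' @export
probability_to_rate <- function(p, time = 1) {
  if (!is.numeric(p) || !is.numeric(time)) {
    stop("`p` and `time` must be numeric", call. = FALSE)
  }
  if (any(p < 0) || any(p >= 1)) stop("`p` must be in [0, 1)", call. = FALSE)
  if (any(time <= 0)) stop("`time` must be positive", call. = FALSE)
  -log(1 - p) / time
}

#' Convert a multi-year risk to an annual probability
#'
#' Solves `1 - (1 - p_annual)^k = p_k` for the per-cycle probability, e.g. to
#' derive annual mortality from a 5-year mortality figure reported by a trial.
#'
#' @param p_k Cumulative probability over `k` years, in `[0, 1)`.
#' @param k Number of years (>= 1).
#' @return Annual probability; compounding it `k` times recovers `p_k`.
#' @export
multiyear_to_annual_probability <- function(p_k, k) {
  if (!is.numeric(p_k) || !is.numeric(k)) {
    stop("`p_k` and `k` must be numeric", call. = FALSE)
  }
  if (any(p_k < 0) || any(p_k >= 1)) stop("`p_k` must be in [0, 1)", call. = FALSE)
  if (any(k < 1)) stop("`k` must be at least 1", call. = FALSE)
  1 - (1 - p_k)^(1 / k)
}

#' Merge independent competing recurrence components
#'
#' Combines annual probabilities of locoregional recurrence, second primary
#' malignancy and distant metastasis into a single annual recurrence
#' probability, treating the components as independent competing events:
#' `1 - (1 - p1)(1 - p2)(1 - p3)`.
#'
#' @param p_locoregional,p_second_primary,p_distant Annual probabilities in
#'   `[0, 1)`.
#' @return Merged annual recurrence probability; at least the largest input
#'   and at most their sum.
#' @export
merge_recurrence <- function(p_locoregional, p_second_primary, p_distant) {
  p <- c(p_locoregional, p_second_primary, p_distant)
  if (!is.numeric(p) || length(p) != 3L) {
    stop("all three components must be scalar numerics", call. = FALSE)
  }
  if (any(p < 0) || any(p >= 1)) {
    stop("recurrence components must be in [0, 1)", call. = FALSE)
  }
  1 - prod(1 - p)
}

# Apply a relative effect to a probability on the rate scale:
# p -> 1 - (1 - p)^rr, i.e. hazard multiplied by rr.
apply_relative_risk <- function(p, rr) {
  if (any(rr < 0)) stop("relative effects must be non-negative", call. = FALSE)
  1 - (1 - p)^rr
}
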