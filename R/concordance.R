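#' Harrell's concordance index for right-censored survival data
#'
#' Computes the fraction of comparable patient pairs whose predicted risk
#' ordering agrees with their observed survival ordering. A pair (i, j) is
#' comparable iff `time[i] < time[j]` and the earlier patient experienced the
#' event (`event[i] == 1`); pairs with tied times are not comparable. A
#' comparable pair is concordant when the earlier-event patient has the
#' higher risk score; tied scores contribute 1/2. A value of 0.5 corresponds
#' to a completely random prognosis, 1.0 to a perfect ordering and 0 to
#' perfect anti-concordance.
#'
#' The package-wide orientation convention is that a higher score means a
#' higher risk, i.e. a shorter expected survival. All model adapters in
#' [predict_risk()] conform to this convention.
#'
#' @param score numeric vector of risk scores (higher = worse prognosis).
#' @param time numeric vector of follow-up times, same length as `score`.
#' @param event integer/logical vector; 1 (TRUE) if the event was observed,
#'   0 (FALSE) if the observation is censored.
#' @return A single number in \[0, 1\].
#' @examples
#' harrell_c(c(3, 2, 1), time = c(1, 2, 3), event = c(1, 1, 1)) # 1
#' harrell_c(c(1, 2, 3), time = c(1, 2, 3), event = c(1, 1, 1)) # 0
#' @export
harrell_c <- function(score, time, event) {
  n <- length(score)
  if (length(time) != n || length(event) != n) {
    stop_sigceiling("sigceiling_length_error",
                    "score, time and event must have equal length")
  }
  if (!all(is.finite(score))) {
    stop_sigceiling("sigceiling_validation_error", "scores must be finite")
  }
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) {
    stop_sigceiling("sigceiling_validation_error",
                    "event must contain only 0/1")
  }
  cnt <- .concordance_counts(as.numeric(score), as.numeric(time), event)
  if (cnt[3] == 0) {
    stop_sigceiling("sigceiling_no_comparable_pairs",
                    "no comparable pair: C-index is undefined")
  }
  unname((cnt[1] + 0.5 * cnt[2]) / cnt[3])
}

# NA-returning variant used inside cross-validation folds: a fold without a
# comparable pair is recorded as a missing cell, not a hard failure.
harrell_c_or_na <- function(score, time, event) {
  tryCatch(harrell_c(score, time, event),
           sigceiling_no_comparable_pairs = function(e) NA_real_)
}
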