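# Shared internal helpers and the fixed annotation category sets.

RELEVANCE_LEVELS <- c("Relevant", "Relevant abroad", "Irrelevant")
SUBJECT_LEVELS <- c("Vaccine", "Disease", "Vaccine and disease")
STANCE_LEVELS <- c("Negative", "Neutral", "Positive", "Not clear")
SENTIMENT_LEVELS <- c("Informative", "Anger/frustration", "Worry/fear/doubts",
                      "Relieved", "Other")
CATEGORIZATIONS <- c("relevance", "subject", "stance", "sentiment")

#' Round half away from zero
#'
#' Decimal rounding with halves going up (0.355 -> 0.36 at two digits), the
#' convention used in all printed reports. Base `round()` rounds halves to
#' even, which would disagree on exact midpoints.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clamp01 <- function(x) pmin(1, pmax(0, x))

clamp_unit <- function(x) pmin(1, pmax(-1, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Probability-field validation with the offending field named in the error.
check_rate <- function(value, field) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < 0 || value > 1) {
    stop("invalid probability for field '", field, "': must be a single value in [0, 1]",
         call. = FALSE)
  }
  invisible(value)
}

#' Percentage removed between two counts
#'
#' Convenience for filter bookkeeping: the percentage of items removed going
#' from `before` to `after`, rounded half-up to whole percent.
#'
#' @param before count before a processing step.
#' @param after count after the step.
#' @return percentage removed, in \[0, 100\].
#' @export
removal_percent <- function(before, after) {
  stopifnot(before > 0, after >= 0, after <= before)
  round_half_up(100 * (before - after) / before, 0)
}
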