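# Rule-based polarity scoring: a weighted lexicon with intensity modifiers,
# product aggregation over the weighted tokens of a message, and calibration
# of the continuous score into discrete stance labels on training data.

#' Polarity lexicon
#'
#' @param weights named numeric vector, token -> polarity weight in \[-1, 1\].
#' @param modifiers named numeric vector, token -> multiplicative factor > 0.
#'   A modifier immediately preceding a weighted token scales that token's
#'   weight ("horribly good" style bigrams act as one unit).
#' @return object of class `polarity_lexicon`.
#' @export
polarity_lexicon <- function(weights = numeric(0), modifiers = numeric(0)) {
  if (length(weights)) {
    stopifnot(!is.null(names(weights)), all(nzchar(names(weights))))
    if (any(weights < -1 | weights > 1)) {
      stop("lexicon weights must lie in [-1, 1]", call. = FALSE)
    }
  }
  if (length(modifiers)) {
    stopifnot(!is.null(names(modifiers)), all(modifiers > 0))
  }
  structure(list(weights = weights, modifiers = modifiers),
            class = "polarity_lexicon")
}

#' @export
print.polarity_lexicon <- function(x, ...) {
  cat(sprintf("Polarity lexicon: %d weighted tokens, %d modifiers\n",
              length(x$weights), length(x$modifiers)))
  invisible(x)
}

#' Score a message with the polarity lexicon
#'
#' Scans the tokens left to right. A modifier immediately preceding a
#' weighted token multiplies that token's weight (clamped to \[-1, 1\]); the
#' pair is consumed as one unit. The message score is the product of all
#' (modified) weights present, clamped to \[-1, 1\]. A message with no
#' weighted tokens scores 0. `aggregate = "mean"` averages the weights
#' instead of multiplying them — a pragmatically motivated alternative, since
#' the product flips sign with every additional negative token.
#'
#' @param lexicon a [polarity_lexicon()].
#' @param tokens lowercase token vector (see [tokenize()]).
#' @param aggregate `"product"` (default) or `"mean"`.
#' @return score in \[-1, 1\].
#' @export
score_text <- function(lexicon, tokens, aggregate = c("product", "mean")) {
  stopifnot(inherits(lexicon, "polarity_lexicon"))
  aggregate <- match.arg(aggregate)
  w <- lexicon$weights
  m <- lexicon$modifiers
  vals <- numeric(0)
  i <- 1L
  n <- length(tokens)
  while (i <= n) {
    tk <- tokens[i]
    if (length(m) && tk %in% names(m) && i < n && tokens[i + 1L] %in% names(w)) {
      vals <- c(vals, clamp_unit(unname(m[tk]) * unname(w[tokens[i + 1L]])))
      i <- i + 2L
    } else if (length(w) && tk %in% names(w)) {
      vals <- c(vals, unname(w[tk]))
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(vals) == 0L) return(0)
  if (aggregate == "product") clamp_unit(prod(vals)) else clamp_unit(mean(vals))
}

#' Calibrate discrete stance thresholds on training scores
#'
#' Grid-searches the cut that maximizes F1 on the Negative category when
#' predicting Negative iff `score <= cut`. Ties are broken toward the cut
#' with higher precision, then the smaller cut. The positive cut is found
#' symmetrically (predict Positive iff `score >= cut`, maximizing Positive
#' F1) when Positive occurs in the labels, and defaults to 0 otherwise.
#'
#' @param scores numeric message scores from [score_text()].
#' @param labels character labels, with the Negative category marked
#'   `"Negative"` (and optionally `"Positive"`).
#' @param grid candidate cuts (default 41 evenly spaced over \[-1, 1\]).
#' @return object of class `discrete_thresholds` with `negative_cut` and
#'   `positive_cut`.
#' @export
calibrate_thresholds <- function(scores, labels,
                                 grid = seq(-1, 1, length.out = 41)) {
  if (length(grid) == 0) stop("configuration error: empty threshold grid", call. = FALSE)
  stopifnot(length(scores) == length(labels))
  if (!any(labels == "Negative") || all(labels == "Negative")) {
    stop("calibration requires at least one Negative and one non-Negative label",
         call. = FALSE)
  }
  prf <- function(pred, truth) {
    tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p = p, r = r, f = f)
  }
  pick <- function(stats_mat, cuts, prefer_small) {
    best_f <- max(stats_mat["f", ])
    cand <- which(stats_mat["f", ] >= best_f - 1e-12)
    best_p <- max(stats_mat["p", cand])
    cand <- cand[stats_mat["p", cand] >= best_p - 1e-12]
    cc <- cuts[cand]
    if (prefer_small) min(cc) else max(cc)
  }
  neg_truth <- labels == "Negative"
  neg_stats <- vapply(grid, function(ct) prf(scores <= ct, neg_truth), numeric(3))
  negative_cut <- pick(neg_stats, grid, prefer_small = TRUE)
  positive_cut <- 0
  if (any(labels == "Positive")) {
    pos_truth <- labels == "Positive"
    pos_stats <- vapply(grid, function(ct) prf(scores >= ct, pos_truth), numeric(3))
    positive_cut <- pick(pos_stats, grid, prefer_small = FALSE)
  }
  positive_cut <- max(positive_cut, negative_cut)
  structure(list(negative_cut = negative_cut, positive_cut = positive_cut),
            class = "discrete_thresholds")
}

#' @export
print.discrete_thresholds <- function(x, ...) {
  cat(sprintf("Discrete stance thresholds: Negative <= %.3f, Positive >= %.3f\n",
              x$negative_cut, x$positive_cut))
  invisible(x)
}

#' Discretize a polarity score into a stance label
#'
#' Negative iff `score <= negative_cut` (boundary inclusive); Positive iff
#' `score >= positive_cut`; Neutral otherwise. When a score satisfies both
#' (equal cuts), Negative takes precedence.
#'
#' @param score numeric score(s) in \[-1, 1\].
#' @param thresholds a [calibrate_thresholds()] result.
#' @return character vector of labels.
#' @export
discretize <- function(score, thresholds) {
  stopifnot(inherits(thresholds, "discrete_thresholds"),
            thresholds$negative_cut <= thresholds$positive_cut)
  ifelse(score <= thresholds$negative_cut, "Negative",
         ifelse(score >= thresholds$positive_cut, "Positive", "Neutral"))
}
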