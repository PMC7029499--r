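# Corpus filtering: the three collection-stage filters (retweets, URLs,
# off-topic blacklist words), applied in that order, with per-query-term
# stage counts.

is_retweet <- function(text) {
  grepl("^rt @", tolower(text))
}

has_url <- function(text) {
  lt <- tolower(text)
  grepl("http", lt, fixed = TRUE) | grepl("www.", lt, fixed = TRUE)
}

has_blacklist_token <- function(text, blacklist) {
  vapply(text, function(tx) any(tokenize(tx) %in% blacklist), logical(1),
         USE.NAMES = FALSE)
}

#' Filter a tweet corpus
#'
#' Applies three per-tweet exclusion predicates in order: (1) retweets, i.e.
#' texts starting with `"RT @"` (case-insensitive); (2) messages containing a
#' URL (substring `"http"` or `"www."` after lowercasing) — these typically
#' share a news headline that does not reflect the sender's stance; (3)
#' messages containing a blacklisted word, matched on whole tokens of the
#' lowercased tokenized text (default: words tied to animal or travel
#' vaccination: "dier", "landbouw", "teek"). Surviving order is preserved.
#' Because each rule is a per-tweet predicate, the kept set does not depend on
#' rule order; the stage counts in the report do follow the stated order.
#'
#' @param tweets data.frame with columns `id`, `text` and optionally
#'   `query_term`.
#' @param blacklist character vector of lowercase tokens to exclude on.
#' @return list with `kept` (the surviving rows of `tweets`) and `report`
#'   (a `filter_report`: per query term and in total, counts before filtering
#'   and after each stage).
#' @export
filter_corpus <- function(tweets, blacklist = BLACKLIST_TOKENS) {
  stopifnot(is.data.frame(tweets), all(c("id", "text") %in% names(tweets)))
  if (!is.null(blacklist) && length(blacklist) &&
      any(blacklist != tolower(blacklist))) {
    stop("blacklist tokens must be lowercase", call. = FALSE)
  }
  n <- nrow(tweets)
  term <- if ("query_term" %in% names(tweets)) {
    ifelse(is.na(tweets$query_term), "(none)", tweets$query_term)
  } else rep("(all)", n)

  rt <- if (n) is_retweet(tweets$text) else logical(0)
  url <- if (n) has_url(tweets$text) else logical(0)
  bl <- if (n) has_blacklist_token(tweets$text, blacklist) else logical(0)

  s1 <- !rt                 # after retweet removal
  s2 <- s1 & !url           # after URL removal
  s3 <- s2 & !bl            # after blacklist removal

  terms <- unique(term)
  rows <- lapply(terms, function(tm) {
    idx <- term == tm
    data.frame(query_term = tm,
               before = sum(idx),
               after_retweets = sum(idx & s1),
               after_urls = sum(idx & s2),
               after_blacklist = sum(idx & s3),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  total <- data.frame(query_term = "Total",
                      before = n,
                      after_retweets = sum(s1),
                      after_urls = sum(s2),
                      after_blacklist = sum(s3),
                      stringsAsFactors = FALSE)
  report <- rbind(report, total)
  class(report) <- c("filter_report", "data.frame")
  list(kept = tweets[s3, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Corpus filter report (counts per stage)\n")
  print.data.frame(x, row.names = FALSE)
  tot <- x[x$query_term == "Total", ]
  if (nrow(tot) == 1 && tot$before > 0) {
    cat(sprintf("Retweet removal: %d%% of messages\n",
                removal_percent(tot$before, tot$after_retweets)))
  }
  invisible(x)
}
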