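# Plain-text interchange: tweets as JSON-lines, annotations and labeled
# instances as CSV, vocabularies and lexica as TSV.

#' Write / read tweets as JSON-lines
#'
#' One JSON object per line with fields `id` and `text` (and `query_term`
#' when present).
#'
#' @param tweets data.frame with columns `id`, `text`.
#' @param path file path.
#' @return `read_tweets_jsonl` returns the tweets data.frame.
#' @export
write_tweets_jsonl <- function(tweets, path) {
  stopifnot(all(c("id", "text") %in% names(tweets)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(tweets))) {
    rec <- as.list(tweets[i, , drop = FALSE])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_tweets_jsonl
#' @export
read_tweets_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(l) {
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read an annotation table as CSV
#'
#' Columns: `tweet_id`, `annotator_id`, `relevance`, `subject`, `stance`,
#' `sentiment`; absent sub-category values are empty cells.
#'
#' @param records annotation data.frame.
#' @param path file path.
#' @return `read_annotations_csv` returns the annotation data.frame.
#' @export
write_annotations_csv <- function(records, path) {
  cols <- c("tweet_id", "annotator_id", CATEGORIZATIONS)
  stopifnot(all(c("tweet_id", "annotator_id", "relevance") %in% names(records)))
  for (cc in setdiff(cols, names(records))) records[[cc]] <- NA_character_
  utils::write.csv(records[cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_annotations_csv
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  stopifnot(all(c("tweet_id", "annotator_id", "relevance") %in% names(df)))
  df
}

#' Write / read labeled instances as CSV
#'
#' Columns: `tweet_id`, `label`, `tier`.
#'
#' @param instances a [harmonize()] result.
#' @param path file path.
#' @return `read_instances_csv` returns the instances data.frame.
#' @export
write_instances_csv <- function(instances, path) {
  stopifnot(all(c("tweet_id", "label", "tier") %in% names(instances)))
  utils::write.csv(as.data.frame(instances)[c("tweet_id", "label", "tier")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_instances_csv
#' @export
read_instances_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  class(df) <- c("labeled_instances", "data.frame")
  df
}

#' Write / read a feature vocabulary as TSV
#'
#' Columns: `feature`, `document_frequency`, `rank`.
#'
#' @param vocab a [build_vocabulary()] result.
#' @param path file path.
#' @return `read_vocabulary_tsv` returns the `feature_vocabulary`.
#' @export
write_vocabulary_tsv <- function(vocab, path) {
  stopifnot(inherits(vocab, "feature_vocabulary"))
  utils::write.table(as.data.frame(vocab), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary_tsv
#' @export
read_vocabulary_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = c("character", "integer", "integer"))
  class(df) <- c("feature_vocabulary", "data.frame")
  df
}

#' Write / read a polarity lexicon as TSV
#'
#' Weights as `token <tab> weight`; modifiers, when present, in a companion
#' file `token <tab> factor`.
#'
#' @param lexicon a [polarity_lexicon()].
#' @param path weights file path.
#' @param modifiers_path optional modifiers file path.
#' @return `read_lexicon_tsv` returns the `polarity_lexicon`.
#' @export
write_lexicon_tsv <- function(lexicon, path, modifiers_path = NULL) {
  stopifnot(inherits(lexicon, "polarity_lexicon"))
  utils::write.table(
    data.frame(token = names(lexicon$weights), weight = unname(lexicon$weights)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(modifiers_path)) {
    utils::write.table(
      data.frame(token = names(lexicon$modifiers),
                 factor = unname(lexicon$modifiers)),
      modifiers_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_lexicon_tsv
#' @export
read_lexicon_tsv <- function(path, modifiers_path = NULL) {
  wdf <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  weights <- stats::setNames(wdf$weight, wdf$token)
  modifiers <- numeric(0)
  if (!is.null(modifiers_path)) {
    mdf <- utils::read.table(modifiers_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "")
    modifiers <- stats::setNames(mdf$factor, mdf$token)
  }
  polarity_lexicon(weights, modifiers)
}

#' Share of doubly-annotated tweets
#'
#' @param records annotation data.frame, or a named pair of counts
#'   (`double`, `total`).
#' @return percentage of annotated tweets coded by two annotators, rounded
#'   half-up to whole percent.
#' @export
double_annotated_percent <- function(records) {
  if (is.data.frame(records)) {
    tab <- table(records$tweet_id)
    double <- sum(tab >= 2L)
    total <- length(tab)
  } else {
    double <- records[["double"]]
    total <- records[["total"]]
  }
  round_half_up(100 * double / total, 0)
}
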