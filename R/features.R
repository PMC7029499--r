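# Tokenization and binary word n-gram features over a frequency-capped
# vocabulary. The tokenizer is rule-based: whitespace split, punctuation runs
# detached, hashtags/mentions/emoticons/URLs kept whole, everything
# lowercased. Punctuation, emoji and emoticons are retained as tokens since
# such markers can be predictive in a charged discussion.

# Punctuation characters that may be detached from a word; '#' and '@' are
# excluded so hashtags and mentions keep their prefix.
.detach_chars <- "[\\!\"\\$%&'\\(\\)\\*\\+,\\-\\./:;<=>\\?\\[\\]\\^_`\\{\\|\\}~…“”‘’]"

.emoticon_re <- "^[:;=8xX][-'o^]?[\\)\\(\\]\\[dDpP3\\*\\|/\\\\<>oO]+$"

#' Tokenize a message
#'
#' Splits on whitespace, detaches leading and trailing punctuation runs as
#' separate tokens, keeps `#hashtags`, `@mentions`, emoticons (`":)"`,
#' `":-("`, ...) and URLs as single tokens, and lowercases everything.
#'
#' @param text a single character string.
#' @return character vector of lowercase tokens; empty for empty text.
#' @export
tokenize <- function(text) {
  if (length(text) != 1L) stop("tokenize() expects a single string", call. = FALSE)
  if (is.na(text)) return(character(0))
  text <- tolower(trimws(text))
  if (!nzchar(text)) return(character(0))
  raw <- strsplit(text, "[[:space:]]+")[[1]]
  out <- vector("list", length(raw))
  for (i in seq_along(raw)) {
    tok <- raw[i]
    if (!nzchar(tok)) next
    if (grepl("^(https?://|www\\.)", tok) || grepl(.emoticon_re, tok, perl = TRUE)) {
      out[[i]] <- tok
      next
    }
    lead <- regmatches(tok, regexpr(paste0("^", .detach_chars, "+"), tok, perl = TRUE))
    core <- if (length(lead)) substring(tok, nchar(lead) + 1L) else tok
    trail <- regmatches(core, regexpr(paste0(.detach_chars, "+$"), core, perl = TRUE))
    if (length(trail)) core <- substring(core, 1L, nchar(core) - nchar(trail))
    # a peeled core can itself be an emoticon-free remnant; emit the pieces
    pieces <- c(if (length(lead)) lead, if (nzchar(core)) core,
                if (length(trail)) trail)
    out[[i]] <- pieces
  }
  unlist(out, use.names = FALSE) %||% character(0)
}

# All word n-grams of a token sequence, joined by "_"; n-grams never cross
# message boundaries and no padding is used.
token_ngrams <- function(tokens, n_range = 1:3) {
  k <- length(tokens)
  if (k == 0L) return(character(0))
  res <- vector("list", length(n_range))
  for (j in seq_along(n_range)) {
    n <- n_range[j]
    if (k < n) next
    if (n == 1L) {
      res[[j]] <- tokens
    } else {
      idx <- seq_len(k - n + 1L)
      parts <- lapply(0:(n - 1L), function(o) tokens[idx + o])
      res[[j]] <- do.call(paste, c(parts, sep = "_"))
    }
  }
  unlist(res, use.names = FALSE) %||% character(0)
}

#' Build the feature vocabulary from training messages
#'
#' Candidate features are all word uni-, bi- and trigrams. They are ranked by
#' document frequency (number of messages containing the feature) in
#' decreasing order, ties broken lexicographically, and the top
#' `max_features` are retained. Features are binary-coded downstream, which
#' makes document frequency the natural notion of "most frequent". The
#' vocabulary must be built on training data only; vectorizing held-out data
#' never extends it.
#'
#' @param token_seqs list of token vectors, one per message.
#' @param max_features maximum vocabulary size (default 15,000).
#' @param n_range n-gram orders to extract.
#' @return object of class `feature_vocabulary`: data.frame with columns
#'   `feature`, `document_frequency`, `rank`.
#' @export
build_vocabulary <- function(token_seqs, max_features = 15000L, n_range = 1:3) {
  stopifnot(is.list(token_seqs), length(token_seqs) > 0, max_features >= 1)
  per_doc <- lapply(token_seqs, function(tk) unique(token_ngrams(tk, n_range)))
  df <- table(unlist(per_doc, use.names = FALSE))
  if (length(df) == 0L) {
    vocab <- data.frame(feature = character(0), document_frequency = integer(0),
                        rank = integer(0), stringsAsFactors = FALSE)
    class(vocab) <- c("feature_vocabulary", "data.frame")
    return(vocab)
  }
  feats <- names(df)
  counts <- as.integer(df)
  ord <- order(-counts, feats, method = "radix")
  keep <- ord[seq_len(min(max_features, length(ord)))]
  vocab <- data.frame(feature = feats[keep],
                      document_frequency = counts[keep],
                      rank = seq_along(keep), stringsAsFactors = FALSE)
  class(vocab) <- c("feature_vocabulary", "data.frame")
  vocab
}

#' @export
print.feature_vocabulary <- function(x, ...) {
  cat(sprintf("Feature vocabulary: %d n-gram features\n", nrow(x)))
  if (nrow(x)) {
    cat("Top features:\n")
    print.data.frame(utils::head(as.data.frame(x), 5), row.names = FALSE)
  }
  invisible(x)
}

#' Binary feature vector for one message
#'
#' Indicator per vocabulary feature: 1 if the n-gram occurs at least once in
#' the message, 0 otherwise. Out-of-vocabulary n-grams are ignored.
#'
#' @param tokens token vector of the message.
#' @param vocab a [build_vocabulary()] result.
#' @return named numeric 0/1 vector of length `nrow(vocab)`.
#' @export
vectorize <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "feature_vocabulary"))
  present <- vocab$feature %in% token_ngrams(tokens)
  stats::setNames(as.numeric(present), vocab$feature)
}

#' Sparse binary feature matrix for a corpus
#'
#' @param token_seqs list of token vectors, one per message.
#' @param vocab a [build_vocabulary()] result.
#' @param ids optional row names (message ids).
#' @return a sparse `dgCMatrix` (messages x features) with 0/1 entries.
#' @export
vectorize_corpus <- function(token_seqs, vocab, ids = NULL) {
  stopifnot(inherits(vocab, "feature_vocabulary"))
  nd <- length(token_seqs)
  nf <- nrow(vocab)
  idx <- lapply(token_seqs, function(tk) {
    which(vocab$feature %in% token_ngrams(tk))
  })
  ii <- rep.int(seq_len(nd), lengths(idx))
  jj <- unlist(idx, use.names = FALSE)
  if (is.null(jj)) jj <- integer(0)
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(nd, nf),
                            dimnames = list(ids, vocab$feature))
  m
}
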