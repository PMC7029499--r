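# Label harmonization: map full annotation profiles to one of four labeling
# granularities, resolve annotator pairs into strict/lax/one reliability
# tiers, and assemble the four training-data variants.

SCHEME_NAMES <- c("binary", "irrelevance_filter", "polarity", "polarity_sentiment")

POLARITY_LABELS <- c("Negative", "Positive", "Neutral", "Not clear", "Irrelevant")
FINEST_LABELS <- c("Negative", "Positive+Frustration", "Positive+Information",
                   "Positive+Other", "Neutral", "Not clear", "Irrelevant")

#' Labeling scheme
#'
#' The four labeling granularities:
#' * `binary`: Negative vs Other;
#' * `irrelevance_filter`: Negative, Irrelevant, Other (other relevant);
#' * `polarity`: Negative, Positive, Neutral, Not clear, Irrelevant;
#' * `polarity_sentiment`: as polarity, with Positive split by sentiment into
#'   Positive+Frustration, Positive+Information and Positive+Other.
#'
#' Each scheme carries a display order (the report layout) and a preference
#' order used for lax labeling. The preference order puts Negative first and
#' Irrelevant last throughout; under the three-way scheme Irrelevant is least
#' preferred (it never wins a lax resolution), consistent with the data-set
#' overview in which the Irrelevant count does not grow from strict to
#' strict+lax. Strictness is assessed at the finest level relevant to the
#' scheme — the polarity level for the first three schemes, the
#' sentiment-split level for `polarity_sentiment` — and then projected, so
#' that coarse strict counts are sums of fine strict counts.
#'
#' @param name one of `"binary"`, `"irrelevance_filter"`, `"polarity"`,
#'   `"polarity_sentiment"`.
#' @return object of class `label_scheme` with elements `name`, `labels`
#'   (display order), `preference` (most preferred first) and `strict_level`.
#' @export
label_scheme <- function(name = SCHEME_NAMES) {
  name <- match.arg(name)
  switch(name,
    binary = structure(list(
      name = "binary",
      labels = c("Negative", "Other"),
      preference = c("Negative", "Other"),
      strict_level = "polarity"), class = "label_scheme"),
    irrelevance_filter = structure(list(
      name = "irrelevance_filter",
      labels = c("Negative", "Irrelevant", "Other"),
      preference = c("Negative", "Other", "Irrelevant"),
      strict_level = "polarity"), class = "label_scheme"),
    polarity = structure(list(
      name = "polarity",
      labels = POLARITY_LABELS,
      preference = c("Negative", "Positive", "Neutral", "Not clear", "Irrelevant"),
      strict_level = "polarity"), class = "label_scheme"),
    polarity_sentiment = structure(list(
      name = "polarity_sentiment",
      labels = FINEST_LABELS,
      preference = FINEST_LABELS,
      strict_level = "polarity_sentiment"), class = "label_scheme")
  )
}

#' @export
print.label_scheme <- function(x, ...) {
  cat(sprintf("Labeling scheme '%s': %s\n", x$name, paste(x$labels, collapse = ", ")))
  cat("  lax preference:", paste(x$preference, collapse = " > "), "\n")
  invisible(x)
}

validate_profile <- function(relevance, subject, stance, sentiment) {
  if (is.na(relevance) || !relevance %in% RELEVANCE_LEVELS) {
    stop("unknown value for field 'relevance': ", relevance, call. = FALSE)
  }
  if (relevance == "Irrelevant") return(invisible(NULL))
  if (!is.na(subject) && !subject %in% SUBJECT_LEVELS) {
    stop("unknown value for field 'subject': ", subject, call. = FALSE)
  }
  if (is.na(stance) || !stance %in% STANCE_LEVELS) {
    stop("unknown value for field 'stance': ", stance, call. = FALSE)
  }
  if (!is.na(sentiment) && !sentiment %in% SENTIMENT_LEVELS) {
    stop("unknown value for field 'sentiment': ", sentiment, call. = FALSE)
  }
  invisible(NULL)
}

# Polarity-level label of a profile (Relevant and Relevant abroad collapse).
profile_polarity_label <- function(relevance, stance) {
  if (relevance == "Irrelevant") "Irrelevant" else stance
}

#' Map a full annotation profile to a scheme label
#'
#' Relevant and Relevant abroad are combined into Relevant. An Irrelevant
#' profile maps to Irrelevant (Other under the binary scheme). A Negative
#' stance maps to Negative under every scheme. Under `polarity_sentiment`
#' a Positive stance splits by the sentiment coding: Anger/frustration ->
#' Positive+Frustration, Informative -> Positive+Information, all others ->
#' Positive+Other.
#'
#' @param profile list or one-row data.frame with `relevance`, `subject`,
#'   `stance`, `sentiment` (sub-fields `NA` iff Irrelevant).
#' @param scheme a [label_scheme()] or scheme name.
#' @return the scheme label (character scalar).
#' @export
map_profile <- function(profile, scheme) {
  if (is.character(scheme)) scheme <- label_scheme(scheme)
  relevance <- profile$relevance
  subject <- profile$subject %||% NA_character_
  stance <- profile$stance %||% NA_character_
  sentiment <- profile$sentiment %||% NA_character_
  validate_profile(relevance, subject, stance, sentiment)
  pol <- profile_polarity_label(relevance, stance)
  project_label(if (scheme$strict_level == "polarity_sentiment")
    profile_finest_label(relevance, stance, sentiment) else pol,
    from = scheme$strict_level, to = scheme$name)
}

#' Project a label between labeling granularities
#'
#' Maps a label of a finer scheme onto a coarser one: the sentiment-split
#' Positive labels collapse to Positive at the polarity level; at the binary
#' level everything but Negative becomes Other; under the irrelevance filter
#' Irrelevant is kept apart and other non-Negative labels become Other.
#'
#' @param label label of the `from` scheme.
#' @param from `"polarity"` or `"polarity_sentiment"`.
#' @param to target scheme name.
#' @return the projected label.
#' @export
project_label <- function(label, from = "polarity_sentiment", to = "binary") {
  from <- match.arg(from, c("polarity", "polarity_sentiment"))
  to <- match.arg(to, SCHEME_NAMES)
  pol <- if (from == "polarity_sentiment") {
    ifelse(label %in% c("Positive+Frustration", "Positive+Information",
                        "Positive+Other"), "Positive", label)
  } else label
  bad <- !pol %in% POLARITY_LABELS
  if (any(bad)) stop("unknown label '", label[bad][1], "' for scheme '", from, "'",
                     call. = FALSE)
  switch(to,
    binary = ifelse(pol == "Negative", "Negative", "Other"),
    irrelevance_filter = ifelse(pol %in% c("Negative", "Irrelevant"), pol, "Other"),
    polarity = pol,
    polarity_sentiment = {
      if (from != "polarity_sentiment")
        stop("cannot project polarity labels up to the sentiment-split scheme",
             call. = FALSE)
      label
    })
}

#' Sum labeled counts of a finer scheme into a coarser scheme
#'
#' Bookkeeping helper: given named per-label counts under one scheme, returns
#' the counts implied under a coarser scheme.
#'
#' @param counts named numeric vector (names = labels of `from`).
#' @param from,to scheme names as in [project_label()].
#' @return named numeric vector over the `to` scheme's labels.
#' @export
project_counts <- function(counts, from = "polarity", to = "binary") {
  to_labels <- project_label(names(counts), from = from, to = to)
  out <- tapply(as.numeric(counts), to_labels, sum)
  res <- stats::setNames(as.numeric(out), names(out))
  res[label_scheme(to)$labels[label_scheme(to)$labels %in% names(res)]]
}

#' Harmonize paired annotations into tiered labeled instances
#'
#' Doubly-annotated tweets whose two labels agree at the scheme's strict
#' level become tier `strict` with that label (projected to the scheme).
#' Doubly-annotated tweets with differing labels become tier `lax`, labeled
#' with the more preferred of the two scheme labels under the scheme's
#' preference order. Singly-annotated tweets become tier `one` with the
#' annotator's mapped label. The three tiers partition the annotated tweets.
#'
#' @param records annotation data.frame (at most two annotators per tweet).
#' @param scheme a [label_scheme()] or scheme name.
#' @return data.frame of class `labeled_instances` with columns `tweet_id`,
#'   `label`, `tier`.
#' @export
harmonize <- function(records, scheme) {
  if (is.character(scheme)) scheme <- label_scheme(scheme)
  stopifnot(is.data.frame(records),
            all(c("tweet_id", "annotator_id", "relevance") %in% names(records)))
  if (anyDuplicated(records[c("tweet_id", "annotator_id")])) {
    stop("at most one record per (tweet_id, annotator_id) is supported", call. = FALSE)
  }
  counts <- table(records$tweet_id)
  if (any(counts > 2L)) {
    stop("unsupported input: tweet(s) with more than two annotators: ",
         names(counts)[counts > 2L][1], call. = FALSE)
  }
  records <- records[order(records$tweet_id, records$annotator_id, method = "radix"), ]
  fine <- vapply(seq_len(nrow(records)), function(i) {
    validate_profile(records$relevance[i], records$subject[i] %||% NA,
                     records$stance[i], records$sentiment[i])
    if (scheme$strict_level == "polarity_sentiment") {
      profile_finest_label(records$relevance[i], records$stance[i],
                           records$sentiment[i])
    } else {
      profile_polarity_label(records$relevance[i], records$stance[i])
    }
  }, character(1))
  mapped <- project_label(fine, from = scheme$strict_level, to = scheme$name)

  sp_fine <- split(fine, records$tweet_id)
  sp_map <- split(mapped, records$tweet_id)
  pref_rank <- stats::setNames(seq_along(scheme$preference), scheme$preference)
  ids <- names(sp_fine)
  label <- character(length(ids))
  tier <- character(length(ids))
  for (i in seq_along(ids)) {
    fl <- sp_fine[[i]]
    ml <- sp_map[[i]]
    if (length(fl) == 1L) {
      tier[i] <- "one"
      label[i] <- ml
    } else if (fl[1] == fl[2]) {
      tier[i] <- "strict"
      label[i] <- ml[1]
    } else {
      tier[i] <- "lax"
      label[i] <- ml[which.min(pref_rank[ml])]
    }
  }
  out <- data.frame(tweet_id = ids, label = label, tier = tier,
                    stringsAsFactors = FALSE)
  attr(out, "scheme") <- scheme$name
  class(out) <- c("labeled_instances", "data.frame")
  out
}

VARIANT_NAMES <- c("strict", "strict+lax", "strict+one", "strict+lax+one")

variant_tiers <- function(variant) {
  variant <- gsub("[ _]", "", tolower(variant))
  variant <- gsub("\\+", "+", variant)
  tiers <- switch(variant,
    "strict" = "strict",
    "strict+lax" = c("strict", "lax"),
    "strict+one" = c("strict", "one"),
    "strict+lax+one" = c("strict", "lax", "one"),
    stop("unknown variant name '", variant, "'", call. = FALSE))
  tiers
}

#' Assemble a training-data variant from tiered instances
#'
#' The four variants combine the reliability tiers: only strict, strict+lax,
#' strict+one, strict+lax+one. The strict tier is present in every variant.
#'
#' @param instances a [harmonize()] result.
#' @param variant one of `"strict"`, `"strict+lax"`, `"strict+one"`,
#'   `"strict+lax+one"`.
#' @return the selected rows, with attribute `variant`.
#' @export
build_variant <- function(instances, variant = VARIANT_NAMES) {
  if (length(variant) > 1L) variant <- variant[1]
  tiers <- variant_tiers(variant)
  out <- instances[instances$tier %in% tiers, , drop = FALSE]
  attr(out, "scheme") <- attr(instances, "scheme")
  attr(out, "variant") <- variant
  out
}

#' Data-set overview: per-label counts by scheme and variant
#'
#' The layout of the study's data-set overview: for each labeling scheme, the
#' count of instances per label under each of the four training-data
#' variants.
#'
#' @param records annotation data.frame.
#' @param schemes scheme names to include.
#' @return data.frame with columns `scheme`, `label` and one column per
#'   variant.
#' @export
dataset_overview <- function(records, schemes = SCHEME_NAMES) {
  rows <- lapply(schemes, function(sn) {
    sch <- label_scheme(sn)
    inst <- harmonize(records, sch)
    cols <- lapply(VARIANT_NAMES, function(vn) {
      v <- build_variant(inst, vn)
      tab <- table(factor(v$label, levels = sch$labels))
      as.integer(tab)
    })
    df <- data.frame(scheme = sn, label = sch$labels, stringsAsFactors = FALSE)
    for (k in seq_along(VARIANT_NAMES)) df[[VARIANT_NAMES[k]]] <- cols[[k]]
    df
  })
  do.call(rbind, rows)
}
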