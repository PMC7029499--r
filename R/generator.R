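# Synthetic corpus generator: tweets plus paired annotations with controlled
# class distribution, inter-annotator agreement and lexical signal strength.
# Every downstream stage (filtering, agreement, harmonization, classification,
# evaluation) is testable on its output without the original annotated data.

#' Default full-profile class distribution
#'
#' One row per generating annotation profile (relevance, subject, stance,
#' sentiment) with its probability. The default follows the strict-tier
#' proportions of the finest labeling in the source data set: Negative 343,
#' Positive+frustration 392, Positive+information 300, Positive+other 620,
#' Neutral 345, Not clear 253, Irrelevant 633 out of 2,886.
#'
#' @return data.frame with columns `relevance`, `subject`, `stance`,
#'   `sentiment`, `prob`.
#' @export
default_profile_distribution <- function() {
  d <- data.frame(
    relevance = c(rep("Relevant", 6), "Irrelevant"),
    subject   = c(rep("Vaccine", 6), NA),
    stance    = c("Negative", "Positive", "Positive", "Positive",
                  "Neutral", "Not clear", NA),
    sentiment = c("Worry/fear/doubts", "Anger/frustration", "Informative",
                  "Other", "Informative", "Other", NA),
    stringsAsFactors = FALSE
  )
  d$prob <- c(343, 392, 300, 620, 345, 253, 633) / 2886
  d
}

#' Default stance confusion model
#'
#' Row-stochastic matrix over the four stance categories used when a deviating
#' second annotator re-draws the stance. The default is uniform: a deviation
#' is an uninformed re-draw, which makes annotator-model expectations (percent
#' agreement, alpha) analytically tractable.
#'
#' @return 4 x 4 row-stochastic matrix with stance dimnames.
#' @export
default_confusion_model <- function() {
  m <- matrix(0.25, 4, 4, dimnames = list(STANCE_LEVELS, STANCE_LEVELS))
  m
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults emulate the study conditions of the monitored Dutch vaccination
#' corpus: 8,259 annotated tweets of which 78% doubly annotated, class
#' proportions from the strict tier, collection-stage artifact rates from the
#' query/filter overview (31% retweets, 58% of the remainder with a URL, 0.5%
#' with a blacklisted word).
#'
#' @param n_tweets number of tweets to generate.
#' @param class_distribution data.frame of full annotation profiles with a
#'   `prob` column summing to 1 (see [default_profile_distribution()]).
#' @param agreement_rate probability that the second annotator copies the
#'   first annotator's labels outright.
#' @param confusion_model row-stochastic matrix over the stance labels used in
#'   `class_distribution`, applied when the second annotator deviates.
#' @param signal_strength fraction of text tokens drawn from the class-specific
#'   vocabulary rather than the shared background vocabulary, in \[0, 1\].
#' @param distractor_rate probability that a tweet's off-signal tokens are a
#'   correlated burst from another class's vocabulary instead of neutral
#'   background words. Emulates stance-confusable wording (sarcasm, quoting
#'   the opposing side) and makes token occurrences correlated within a
#'   message, as in real text. Independently of this rate, a message whose
#'   second annotator deviates to a different label always draws its
#'   off-signal tokens from that perceived class's vocabulary: disagreement
#'   marks genuinely ambiguous text. At `signal_strength = 1` there are no
#'   off-signal positions and the corpus stays separable.
#' @param burst_size number of distinct vocabulary tokens a single message
#'   draws its class (and distractor) tokens from; small values give the
#'   bursty, topically focused token statistics of real short messages.
#' @param artifact_rates named probabilities `retweet`, `url`, `blacklist` of
#'   the corresponding filterable artifact appearing in a tweet.
#' @param single_annotation_rate probability a tweet receives one annotator
#'   instead of two.
#' @param relevance_flip probability that a deviating second annotator flips
#'   the relevance judgement (Relevant <-> Irrelevant); kept small so stance
#'   disagrees more often than relevance.
#' @param class_vocab_size tokens in each class-specific vocabulary.
#' @param background_vocab_size tokens in the shared background vocabulary.
#' @param seed master seed; per-tweet sub-streams are derived from it so that
#'   enlarging the corpus never reshuffles earlier tweets.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_tweets = 8259,
                             class_distribution = default_profile_distribution(),
                             agreement_rate = 0.40,
                             confusion_model = default_confusion_model(),
                             signal_strength = 0.5,
                             distractor_rate = 0.5,
                             burst_size = 4,
                             artifact_rates = c(retweet = 0.31, url = 0.58,
                                                blacklist = 0.005),
                             single_annotation_rate = 0.22,
                             relevance_flip = 0.15,
                             class_vocab_size = 40,
                             background_vocab_size = 300,
                             seed = 1) {
  if (!is.numeric(n_tweets) || n_tweets < 1) {
    stop("invalid value for field 'n_tweets': must be a positive count", call. = FALSE)
  }
  stopifnot(is.data.frame(class_distribution),
            all(c("relevance", "stance", "sentiment", "prob") %in%
                  names(class_distribution)))
  if (abs(sum(class_distribution$prob) - 1) > 1e-9) {
    stop("invalid value for field 'class_distribution': probabilities must sum to 1",
         call. = FALSE)
  }
  if (any(class_distribution$prob < 0)) {
    stop("invalid probability for field 'class_distribution': negative entry",
         call. = FALSE)
  }
  check_rate(agreement_rate, "agreement_rate")
  check_rate(signal_strength, "signal_strength")
  check_rate(distractor_rate, "distractor_rate")
  stopifnot(burst_size >= 1)
  check_rate(single_annotation_rate, "single_annotation_rate")
  check_rate(relevance_flip, "relevance_flip")
  for (f in c("retweet", "url", "blacklist")) {
    check_rate(unname(artifact_rates[f]), paste0("artifact_rates[", f, "]"))
  }
  stopifnot(is.matrix(confusion_model),
            !is.null(rownames(confusion_model)),
            identical(rownames(confusion_model), colnames(confusion_model)))
  if (any(abs(rowSums(confusion_model) - 1) > 1e-9) || any(confusion_model < 0)) {
    stop("invalid value for field 'confusion_model': rows must be stochastic",
         call. = FALSE)
  }
  stances_used <- unique(stats::na.omit(class_distribution$stance))
  if (!all(stances_used %in% rownames(confusion_model))) {
    stop("invalid value for field 'confusion_model': missing row for a stance in ",
         "'class_distribution'", call. = FALSE)
  }
  structure(list(
    n_tweets = as.integer(n_tweets),
    class_distribution = class_distribution,
    agreement_rate = agreement_rate,
    confusion_model = confusion_model,
    signal_strength = signal_strength,
    distractor_rate = distractor_rate,
    burst_size = as.integer(burst_size),
    artifact_rates = artifact_rates,
    single_annotation_rate = single_annotation_rate,
    relevance_flip = relevance_flip,
    class_vocab_size = as.integer(class_vocab_size),
    background_vocab_size = as.integer(background_vocab_size),
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Finest-granularity label of a generating profile (stance, with the Positive
# class split by sentiment). Shared with the harmonization module.
profile_finest_label <- function(relevance, stance, sentiment) {
  if (relevance == "Irrelevant") return("Irrelevant")
  switch(stance,
         "Negative" = "Negative",
         "Neutral" = "Neutral",
         "Not clear" = "Not clear",
         "Positive" = switch(sentiment,
                             "Anger/frustration" = "Positive+Frustration",
                             "Informative" = "Positive+Information",
                             "Positive+Other"),
         stop("unknown stance value '", stance, "'", call. = FALSE))
}

class_vocabulary <- function(label, size) {
  if (size < 1) return(character(0))
  slug <- gsub("[^a-z]", "", tolower(label))
  sprintf("%s%03d", slug, seq_len(size))
}

background_vocabulary <- function(size) {
  if (size < 1) return(character(0))
  sprintf("achtergrond%03d", seq_len(size))
}

BLACKLIST_TOKENS <- c("dier", "landbouw", "teek")

# Second-annotator deviation: relevance flips with a small probability; when
# the tweet stays relevant the stance is re-drawn from the confusion model row
# and the sentiment is re-drawn uniformly.
deviate_profile <- function(profile, config) {
  out <- profile
  relevant <- profile$relevance != "Irrelevant"
  if (stats::runif(1) < config$relevance_flip) relevant <- !relevant
  if (!relevant) {
    out$relevance <- "Irrelevant"
    out$subject <- out$stance <- out$sentiment <- NA_character_
    return(out)
  }
  out$relevance <- "Relevant"
  cm <- config$confusion_model
  if (!is.na(profile$stance)) {
    out$stance <- sample(colnames(cm), 1, prob = cm[profile$stance, ])
    out$subject <- profile$subject
  } else {
    # originally irrelevant, flipped to relevant: uninformed draw
    out$stance <- sample(colnames(cm), 1)
    out$subject <- "Vaccine"
  }
  out$sentiment <- sample(SENTIMENT_LEVELS, 1)
  out
}

#' Generate a synthetic doubly-annotated tweet corpus
#'
#' Draws, for each tweet, a full annotation profile from the configured class
#' distribution, a bag of 8-25 tokens mixing the class vocabulary with the
#' background vocabulary according to `signal_strength`, optional filterable
#' artifacts (a literal `"RT @"` prefix, an `"http"` URL token, a blacklisted
#' word), and one or two annotators. The second annotator copies the first
#' with probability `agreement_rate` and otherwise deviates through the
#' confusion model.
#'
#' Determinism: the same config (including seed) yields a byte-identical
#' corpus, and per-tweet sub-streams make the first `k` tweets invariant to
#' increases of `n_tweets`.
#'
#' @param config a [generator_config()].
#' @return object of class `synthetic_corpus`: list with `tweets` (data.frame
#'   `id`, `text`), `annotations` (data.frame `tweet_id`, `annotator_id`,
#'   `relevance`, `subject`, `stance`, `sentiment`) and `truth` (data.frame
#'   `tweet_id`, profile columns, finest `label`).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_tweets
  dist <- config$class_distribution
  labels_finest <- vapply(seq_len(nrow(dist)), function(k) {
    profile_finest_label(dist$relevance[k], dist$stance[k], dist$sentiment[k])
  }, character(1))
  vocabs <- lapply(labels_finest, class_vocabulary, size = config$class_vocab_size)
  bg <- background_vocabulary(config$background_vocab_size)

  set.seed(config$seed)
  tweet_seeds <- sample.int(2147483646L, n, replace = TRUE)

  ids <- sprintf("t%06d", seq_len(n))
  texts <- character(n)
  truth <- vector("list", n)
  ann <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(tweet_seeds[i])
    k <- sample.int(nrow(dist), 1, prob = dist$prob)
    profile <- list(relevance = dist$relevance[k], subject = dist$subject[k],
                    stance = dist$stance[k], sentiment = dist$sentiment[k])
    # annotator behavior first: disagreement marks an ambiguous message, and
    # ambiguity is reflected in the text below
    single <- stats::runif(1) < config$single_annotation_rate
    p2 <- NULL
    if (!single) {
      p2 <- if (stats::runif(1) < config$agreement_rate) profile else
        deviate_profile(profile, config)
    }
    perceived2 <- if (!is.null(p2)) {
      profile_finest_label(p2$relevance, p2$stance, p2$sentiment)
    } else NA_character_
    ntok <- sample(8:25, 1)
    from_class <- stats::runif(ntok) < config$signal_strength
    cv <- vocabs[[k]]
    toks <- character(ntok)
    n_class <- sum(from_class)
    if (n_class > 0 && length(cv) > 0) {
      # bursty: one message draws from a small topical subset of its class vocab
      sub <- sample(cv, min(config$burst_size, length(cv)))
      toks[from_class] <- sample(sub, n_class, replace = TRUE)
    } else {
      from_class[] <- FALSE
    }
    n_off <- sum(!from_class)
    if (n_off > 0) {
      distract <- stats::runif(1) < config$distractor_rate && nrow(dist) > 1L &&
        config$class_vocab_size > 0
      ambiguous <- !is.na(perceived2) && perceived2 != labels_finest[k]
      if (ambiguous && config$class_vocab_size > 0) {
        # a disagreed-upon message reads like the second annotator's class too
        dv <- class_vocabulary(perceived2, config$class_vocab_size)
        dsub <- sample(dv, min(config$burst_size, length(dv)))
        toks[!from_class] <- sample(dsub, n_off, replace = TRUE)
      } else if (distract) {
        dk <- sample(setdiff(seq_len(nrow(dist)), k), 1)
        dv <- vocabs[[dk]]
        dsub <- sample(dv, min(config$burst_size, length(dv)))
        toks[!from_class] <- sample(dsub, n_off, replace = TRUE)
      } else if (length(bg)) {
        toks[!from_class] <- sample(bg, n_off, replace = TRUE)
      } else {
        toks[!from_class] <- "leeg"
      }
    }
    if (stats::runif(1) < config$artifact_rates[["blacklist"]]) {
      toks[sample.int(ntok, 1)] <- sample(BLACKLIST_TOKENS, 1)
    }
    text <- paste(toks, collapse = " ")
    if (stats::runif(1) < config$artifact_rates[["url"]]) {
      text <- paste(text, sprintf("http://t.co/%06d", sample.int(999999L, 1)))
    }
    if (stats::runif(1) < config$artifact_rates[["retweet"]]) {
      text <- paste0("RT @gebruiker", sample.int(999L, 1), ": ", text)
    }
    texts[i] <- text
    truth[[i]] <- data.frame(tweet_id = ids[i], relevance = profile$relevance,
                             subject = profile$subject, stance = profile$stance,
                             sentiment = profile$sentiment,
                             label = labels_finest[k], stringsAsFactors = FALSE)
    a1 <- data.frame(tweet_id = ids[i], annotator_id = "A1",
                     relevance = profile$relevance, subject = profile$subject,
                     stance = profile$stance, sentiment = profile$sentiment,
                     stringsAsFactors = FALSE)
    if (single) {
      ann[[i]] <- a1
    } else {
      a2 <- data.frame(tweet_id = ids[i], annotator_id = "A2",
                       relevance = p2$relevance, subject = p2$subject,
                       stance = p2$stance, sentiment = p2$sentiment,
                       stringsAsFactors = FALSE)
      ann[[i]] <- rbind(a1, a2)
    }
  }

  structure(list(
    tweets = data.frame(id = ids, text = texts, stringsAsFactors = FALSE),
    annotations = do.call(rbind, ann),
    truth = do.call(rbind, truth),
    config = config
  ), class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  n2 <- sum(table(x$annotations$tweet_id) == 2L)
  cat("Synthetic tweet corpus\n")
  cat(sprintf("  tweets:      %d\n", nrow(x$tweets)))
  cat(sprintf("  annotations: %d (%d tweets doubly annotated)\n",
              nrow(x$annotations), n2))
  cat("  truth labels:", paste(names(sort(table(x$truth$label),
                                          decreasing = TRUE)), collapse = ", "), "\n")
  invisible(x)
}

#' Generate a polarity lexicon matched to the synthetic vocabularies
#'
#' Tokens of the Negative-class vocabulary receive negative weights and tokens
#' of the Positive-class vocabularies positive weights, so the rule-based
#' scorer has signal on generated corpora. A sample of background tokens gets
#' small weights of mixed sign, emulating the noise of a general-purpose
#' polarity list. A fixed set of Dutch intensity modifiers is included.
#'
#' @param config a [generator_config()]; determinism follows its seed.
#' @return a [polarity_lexicon()] object.
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed((config$seed %% 2100000000L) + 7919L)
  neg <- class_vocabulary("Negative", config$class_vocab_size)
  pos <- c(class_vocabulary("Positive+Frustration", config$class_vocab_size),
           class_vocabulary("Positive+Information", config$class_vocab_size),
           class_vocabulary("Positive+Other", config$class_vocab_size))
  bg <- background_vocabulary(config$background_vocab_size)
  weights <- numeric(0)
  if (length(neg)) weights[neg] <- stats::runif(length(neg), -0.9, -0.4)
  if (length(pos)) weights[pos] <- stats::runif(length(pos), 0.4, 0.9)
  if (length(bg)) {
    noisy <- sample(bg, max(0L, length(bg) %/% 10L))
    if (length(noisy)) weights[noisy] <- stats::runif(length(noisy), -0.15, 0.15)
  }
  modifiers <- c(zeer = 1.5, erg = 1.3, nogal = 0.8, amper = 0.5)
  if (length(weights) == 0) modifiers <- modifiers[0]
  polarity_lexicon(weights, modifiers)
}
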