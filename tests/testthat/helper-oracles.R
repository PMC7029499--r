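# Independent oracles and small fixture builders shared across test files.

# Annotation records for paired stance labels: one doubly-annotated unit per
# element of `a`/`b`; `singles` adds singly-annotated units.
stance_pair_records <- function(a, b, singles = character(0)) {
  n <- length(a)
  stopifnot(length(b) == n)
  rows <- list()
  for (i in seq_len(n)) {
    rows[[length(rows) + 1L]] <- data.frame(
      tweet_id = sprintf("u%03d", i), annotator_id = c("A1", "A2"),
      relevance = "Relevant", subject = "Vaccine",
      stance = c(a[i], b[i]), sentiment = "Informative",
      stringsAsFactors = FALSE)
  }
  for (j in seq_along(singles)) {
    rows[[length(rows) + 1L]] <- data.frame(
      tweet_id = sprintf("s%03d", j), annotator_id = "A1",
      relevance = "Relevant", subject = "Vaccine",
      stance = singles[j], sentiment = "Informative",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Brute-force Krippendorff alpha (nominal): enumerate all ordered value pairs
# within each unit, weight 1/(m-1), no coincidence-matrix algebra.
alpha_brute_force <- function(units) {
  us <- units[lengths(units) >= 2L]
  n <- 0
  dis <- 0
  for (v in us) {
    m <- length(v)
    n <- n + m
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j && v[i] != v[j]) dis <- dis + 1 / (m - 1)
      }
    }
  }
  nc <- table(unlist(us))
  d_obs <- dis / n
  d_exp <- (n^2 - sum(nc^2)) / (n * (n - 1))
  1 - d_obs / d_exp
}

# Brute-force AUC: O(n^2) pairwise concordance with ties counted one half.
auc_brute_force <- function(scores, positive) {
  sp <- scores[positive]
  sn <- scores[!positive]
  tot <- 0
  for (p in sp) {
    for (q in sn) {
      tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  tot / (length(sp) * length(sn))
}

# Small separable two-class design: one indicator feature per class.
separable_toy <- function(n_per_class = 10) {
  x <- rbind(cbind(rep(1, n_per_class), rep(0, n_per_class)),
             cbind(rep(0, n_per_class), rep(1, n_per_class)))
  colnames(x) <- c("neg_marker", "other_marker")
  list(x = x, y = rep(c("Negative", "Other"), each = n_per_class))
}

# Small synthetic corpus without collection artifacts, for pipeline tests.
clean_corpus <- function(n = 400, seed = 3, ...) {
  generate_corpus(generator_config(
    n_tweets = n, artifact_rates = c(retweet = 0, url = 0, blacklist = 0),
    seed = seed, ...))
}

texts_of <- function(corpus) stats::setNames(corpus$tweets$text, corpus$tweets$id)
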