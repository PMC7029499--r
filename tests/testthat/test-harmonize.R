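# Harmonization: profile-to-scheme mapping, strict/lax/one tier resolution,
# training-data variants and count bookkeeping.

rel_profile <- function(stance, sentiment = "Informative",
                        relevance = "Relevant") {
  list(relevance = relevance, subject = "Vaccine",
       stance = if (relevance == "Irrelevant") NA_character_ else stance,
       sentiment = if (relevance == "Irrelevant") NA_character_ else sentiment)
}

pair_records <- function(p1, p2 = NULL, id = "t1") {
  row <- function(p, aid) data.frame(
    tweet_id = id, annotator_id = aid, relevance = p$relevance,
    subject = p$subject, stance = p$stance, sentiment = p$sentiment,
    stringsAsFactors = FALSE)
  if (is.null(p2)) row(p1, "A1") else rbind(row(p1, "A1"), row(p2, "A2"))
}

test_that("profiles map to the documented labels under all four schemes", {
  neg <- rel_profile("Negative")
  for (sn in c("binary", "irrelevance_filter", "polarity", "polarity_sentiment")) {
    expect_equal(map_profile(neg, sn), "Negative")
  }
  irr <- rel_profile(NA, relevance = "Irrelevant")
  expect_equal(map_profile(irr, "binary"), "Other")
  expect_equal(map_profile(irr, "irrelevance_filter"), "Irrelevant")
  expect_equal(map_profile(irr, "polarity"), "Irrelevant")
  expect_equal(map_profile(irr, "polarity_sentiment"), "Irrelevant")

  pos_inf <- rel_profile("Positive", "Informative")
  expect_equal(map_profile(pos_inf, "polarity_sentiment"), "Positive+Information")
  expect_equal(map_profile(pos_inf, "polarity"), "Positive")
  expect_equal(map_profile(rel_profile("Positive", "Anger/frustration"),
                           "polarity_sentiment"), "Positive+Frustration")
  expect_equal(map_profile(rel_profile("Positive", "Relieved"),
                           "polarity_sentiment"), "Positive+Other")
  # Relevant abroad collapses into Relevant
  expect_equal(map_profile(rel_profile("Neutral", relevance = "Relevant abroad"),
                           "polarity"), "Neutral")
})

test_that("unknown category values raise a validation error naming the field", {
  expect_error(map_profile(rel_profile("Meh"), "binary"), "stance")
  expect_error(map_profile(list(relevance = "Sideways"), "binary"), "relevance")
})

test_that("agreeing pairs are strict, disagreeing pairs take the preferred label", {
  expect_equal(harmonize(pair_records(rel_profile("Negative"),
                                      rel_profile("Negative")), "polarity")$tier,
               "strict")
  lax <- harmonize(pair_records(rel_profile("Positive"), rel_profile("Neutral")),
                   "polarity")
  expect_equal(lax$tier, "lax")
  expect_equal(lax$label, "Positive")
  one <- harmonize(pair_records(rel_profile("Neutral")), "polarity")
  expect_equal(one$tier, "one")
  expect_equal(one$label, "Neutral")
  # an Irrelevant judgement loses against any stance-bearing label
  mixed <- harmonize(pair_records(rel_profile(NA, relevance = "Irrelevant"),
                                  rel_profile("Not clear")), "polarity")
  expect_equal(mixed$label, "Not clear")
  # and also under the three-way scheme (no lax Irrelevant ever)
  mixed3 <- harmonize(pair_records(rel_profile(NA, relevance = "Irrelevant"),
                                   rel_profile("Neutral")), "irrelevance_filter")
  expect_equal(mixed3$label, "Other")
})

test_that("strictness is resolved at the fine level before projection", {
  # Positive vs Neutral agree as Other under binary, but the pair is lax
  rec <- pair_records(rel_profile("Positive"), rel_profile("Neutral"))
  h <- harmonize(rec, "binary")
  expect_equal(h$tier, "lax")
  expect_equal(h$label, "Other")
  # sentiment-level disagreement within Positive is lax only under the split scheme
  rec2 <- pair_records(rel_profile("Positive", "Informative"),
                       rel_profile("Positive", "Relieved"))
  expect_equal(harmonize(rec2, "polarity")$tier, "strict")
  h2 <- harmonize(rec2, "polarity_sentiment")
  expect_equal(h2$tier, "lax")
  expect_equal(h2$label, "Positive+Information")
})

test_that("more than two annotators is rejected", {
  rec <- rbind(pair_records(rel_profile("Negative"), rel_profile("Negative")),
               data.frame(tweet_id = "t1", annotator_id = "A3",
                          relevance = "Relevant", subject = "Vaccine",
                          stance = "Negative", sentiment = "Informative",
                          stringsAsFactors = FALSE))
  expect_error(harmonize(rec, "binary"), "more than two annotators")
})

test_that("variants take unions of tiers and strict is always included", {
  inst <- data.frame(
    tweet_id = sprintf("t%02d", 1:18),
    label = "Negative",
    tier = c(rep("strict", 10), rep("lax", 5), rep("one", 3)),
    stringsAsFactors = FALSE)
  class(inst) <- c("labeled_instances", "data.frame")
  expect_equal(nrow(build_variant(inst, "strict")), 10)
  expect_equal(nrow(build_variant(inst, "strict+lax")), 15)
  expect_equal(nrow(build_variant(inst, "strict+one")), 13)
  expect_equal(nrow(build_variant(inst, "strict+lax+one")), 18)
  expect_error(build_variant(inst, "lax+one"), "unknown variant")
})

test_that("tiers partition the corpus and Negative counts agree across schemes", {
  co <- clean_corpus(n = 800, seed = 61)
  per_scheme <- lapply(c("binary", "irrelevance_filter", "polarity",
                         "polarity_sentiment"),
                       function(sn) harmonize(co$annotations, sn))
  for (inst in per_scheme) {
    tiers <- split(inst$tweet_id, inst$tier)
    expect_equal(sum(lengths(tiers)), length(unique(co$annotations$tweet_id)))
    for (i in seq_along(tiers)) {
      for (j in seq_along(tiers)) {
        if (i < j) expect_length(intersect(tiers[[i]], tiers[[j]]), 0)
      }
    }
  }
  # Negative stability: identical Negative count per tier under every scheme
  neg_by_tier <- lapply(per_scheme, function(inst) {
    table(factor(inst$tier[inst$label == "Negative"],
                 levels = c("strict", "lax", "one")))
  })
  for (k in 2:length(neg_by_tier)) expect_equal(neg_by_tier[[k]], neg_by_tier[[1]])
})

test_that("coarse strict counts equal sums of fine strict counts", {
  co <- clean_corpus(n = 800, seed = 67)
  pol <- harmonize(co$annotations, "polarity")
  bin <- harmonize(co$annotations, "binary")
  irr <- harmonize(co$annotations, "irrelevance_filter")
  strict_counts <- function(inst) {
    tab <- table(inst$label[inst$tier == "strict"])
    stats::setNames(as.numeric(tab), names(tab))
  }
  pc <- strict_counts(pol)
  expect_equal(project_counts(pc, from = "polarity", to = "binary"),
               strict_counts(bin)[names(project_counts(pc, "polarity", "binary"))])
  expect_equal(project_counts(pc, from = "polarity", to = "irrelevance_filter"),
               strict_counts(irr)[names(project_counts(pc, "polarity",
                                                       "irrelevance_filter"))])
})

test_that("any two distinct labels have a strict preference order", {
  for (sn in c("binary", "irrelevance_filter", "polarity", "polarity_sentiment")) {
    sch <- label_scheme(sn)
    expect_setequal(sch$preference, sch$labels)
    expect_equal(anyDuplicated(sch$preference), 0)
  }
})

test_that("the dataset overview has the documented shape", {
  co <- clean_corpus(n = 400, seed = 71)
  ov <- dataset_overview(co$annotations)
  expect_equal(nrow(ov), 2 + 3 + 5 + 7)
  expect_true(all(c("strict", "strict+lax", "strict+one", "strict+lax+one")
                  %in% names(ov)))
  # strict column is bounded by every other variant column
  expect_true(all(ov$strict <= ov$`strict+lax`))
  expect_true(all(ov$strict <= ov$`strict+one`))
})
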