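---
title: "Monitoring negative stance towards vaccination: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring negative stance towards vaccination: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Public-health institutes monitor social media for signs of vaccine
hesitancy. General-purpose sentiment analysis performs poorly on this task
because *stance* — the author's position towards vaccination — is not the
same as the surface sentiment of the words used: a message can be angrily
worded yet pro-vaccination (frustration with anti-vaccination arguments),
or politely worded yet firmly against. `vaxstance` implements a complete
surveillance pipeline oriented at detecting messages with a **negative
stance**: corpus filtering, annotation-reliability analysis, harmonization
of doubly-coded data into training sets of graded reliability, n-gram
classifiers with calibrated probabilities, a lexicon-based polarity scorer,
ensembles of the two, and a precision/recall-oriented evaluation battery.

Because the original annotated tweet corpus cannot be redistributed with
the package, a synthetic-corpus generator reproduces its statistical
conditions, so that every stage is exercised end to end by the test suite.

## Pipeline stages

### Collection-stage filtering

Three per-message exclusion rules are applied in order: retweets (text
beginning `"RT @"`, case-insensitive), messages containing a URL
(lowercased substring `"http"` or `"www."`), and messages containing a
blacklisted word matched on whole tokens (`dier`, `landbouw`, `teek` —
words tied to animal or travel vaccination, outside the national
immunization program). Retweet detection by prefix is a deliberate
narrowing: quote-style retweets without the classic marker are kept.
Substring URL matching covers shortened links without a URL grammar.
Whole-token blacklist matching avoids false hits inside longer words. Each
rule is a per-message predicate, so membership of the surviving set does
not depend on rule order; only the staged counts in the report do.

### Agreement analysis

Annotators code four categorizations per message: relevance
(Relevant / Relevant abroad / Irrelevant), subject, stance
(Negative / Neutral / Positive / Not clear) and sentiment (Informative /
Anger-frustration / Worry-fear-doubts / Relieved / Other). Sub-categories
are structurally absent for Irrelevant messages. Three statistics are
provided:

* **percent agreement** over doubly-annotated units;
* **Krippendorff's alpha** (nominal metric), `1 - Do/De` over the
  coincidence matrix, which tolerates singly-annotated units and varying
  annotator pairs;
* **mutual F-scores** per category, treating one annotator as truth and
  the other as prediction. F1 is invariant under exchanging the roles
  (true positives are fixed, false positives and false negatives swap),
  which the implementation asserts.

Absent sub-category values are treated as *missing* by default, not as an
extra label; the `absent_label` argument switches to the fifth-value
coding. Alpha is reported as an error, not a silent 1.0, when only one
category is observed (expected disagreement zero).

### Harmonization into reliability tiers

Doubly-annotated messages whose labels agree become the **strict** tier;
disagreeing pairs become **lax**, resolved by a fixed category-preference
order (Negative first, Irrelevant last); singly-annotated messages form
the **one** tier. The three tiers partition the corpus. Four labeling
granularities are supported (binary, irrelevance filter, polarity,
polarity + sentiment), and agreement is assessed at the finest level
relevant to a scheme before projecting to it. This makes coarse strict
counts exact sums of fine strict counts — e.g. the binary Other strict
count equals the sum of the non-Negative polarity strict counts.

Two design points deserve note. First, under the three-way irrelevance
filter the preference order is Negative > Other > Irrelevant: an
Irrelevant judgement never wins a lax resolution, consistent with the
stance-bearing preference rule and with the observation that the
Irrelevant count does not grow from strict to strict+lax. Second, under
the sentiment-split scheme a pair agreeing on Positive but disagreeing on
sentiment is lax for that scheme while strict under polarity; the two
schemes' lax counts therefore need not be nested, which is an inherent
property of per-scheme lax resolution.

### Features and classifiers

Messages are tokenized by rule (whitespace split, punctuation runs
detached, hashtags/mentions/emoticons/URLs kept whole, lowercasing);
binary word uni/bi/trigram indicators are built over a vocabulary capped
at the 15,000 features with highest document frequency, ties broken
lexicographically for reproducibility. The vocabulary is rebuilt on each
training fold only, so held-out data never leak into it.

`stance_model()` fits either classifier:

* **Multinomial naive Bayes** with smoothing 0.0 and a uniform ("muted")
  class prior. Zero-count feature likelihoods substitute a configurable
  epsilon (1e-10) so no log of zero is taken — the numerically defined
  reading of literal zero smoothing.
* **Linear SVM** (libsvm via e1071) with C = 1.0 and balanced class
  weights, decomposed one-vs-rest so each class has its own ranking
  score. Per-class probabilities come from Platt-style logistic
  calibration of the decision values, fitted on the training fold, then
  normalized across classes. When the calibration glm degenerates
  (perfect separation), a fixed-slope sigmoid on standardized decision
  values is used instead.

Balanced weights in each one-vs-rest subproblem are `n/(2*n_pos)` and
`n/(2*n_rest)`. The decided label is the probability argmax;
`predict_with_threshold()` overrides it for a chosen target class, which
is how the precision/recall balance is steered.

### Rule-based polarity scoring

The lexicon scorer assigns each message the product of the weights of its
lexicon tokens, with a modifier token immediately preceding a weighted
token multiplying that weight ("horribly good" as one unit); weights and
the final score are clamped to [-1, 1], and a message without weighted
tokens scores 0. Product semantics mean two negative-weight tokens yield a
positive score; this is implemented as specified, with a mean-aggregation
mode available for comparison. The continuous score is discretized by
cuts calibrated on training data: the Negative cut maximizes Negative F1
(predicting Negative iff score <= cut) over a grid of 41 evenly spaced
cuts in [-1, 1]; ties prefer higher precision, then the smaller cut; the
boundary is inclusive.

### Evaluation

All systems are evaluated by stratified 10-fold (configurable)
cross-validation **on the strict tier only**; lax/one data only ever
augment the training side, which the tier partition guarantees and the
runner asserts every fold. Confusion counts are pooled over folds and the
AUC (Mann-Whitney formulation, ties one half) is computed on pooled
out-of-fold probabilities — pooling, rather than averaging, matches the
convention of reporting one overall confusion table. Report rounding is
two decimals, half-up. The grid runner enumerates all
4 schemes x 4 variants x 2 classifiers = 32 systems. Random baselines
label each message Negative with a fixed rate and draw uniform ranking
scores, averaged over seeded repeats. Ensembles of two binary Negative
predictions are the conjunction (precision-oriented) or disjunction
(recall-oriented). The learning curve holds out a stratified 10% strict
test split and trains on nested subsets of the remaining pool — strict
plus lax by default, configurable via `pool_tiers`.

## The synthetic-corpus generator

`generator_config()` defaults are the package's reference study
conditions:

| parameter | default | rationale |
|---|---|---|
| `n_tweets` | 8259 | size of the annotated corpus being emulated |
| `class_distribution` | strict-tier proportions (Negative 343/2886, ..., Irrelevant 633/2886) | observed label marginals |
| `single_annotation_rate` | 0.22 | 78% of messages doubly annotated |
| `agreement_rate` | 0.40 | with uniform stance confusion this yields stance percent agreement of about 0.40 + 0.60/4 = 0.55, the observed regime |
| `relevance_flip` | 0.15 | relevance disagrees less than stance |
| `artifact_rates` | retweet 0.31, url 0.58, blacklist 0.005 | collection-stage removal fractions |
| `signal_strength` | 0.5 | mid-noise: half the tokens carry class signal |
| `distractor_rate` | 0.5 | half the off-signal content is stance-confusable rather than neutral |
| `burst_size` | 4 | short messages draw tokens from a small topical subset |

Each message samples a full annotation profile, 8–25 tokens, optional
artifacts, and one or two annotators; a deviating second annotator
re-draws the stance from a row-stochastic confusion model (uniform by
default), re-draws the sentiment, and flips relevance with small
probability. Annotators are treated as exchangeable, since no
per-annotator bias estimates are available. Seeding uses one master seed
with per-message sub-streams, so enlarging a corpus never reshuffles
earlier messages.

The *text* model matters for what the benchmark can show. A pure
independent-token bag-of-words makes multinomial naive Bayes the
Bayes-optimal classifier by construction, so a discriminative/generative
comparison on such data is vacuous. The generator therefore draws each
message's class tokens from a small per-message topical subset
(burstiness) and, with probability `distractor_rate`, fills the off-signal
positions with a correlated burst from *another* class's vocabulary —
emulating sarcasm and quoting of the opposing side, which are prominent
failure modes in real stance data. This induces correlated features, the
regime in which margin-based classifiers are known to outperform naive
Bayes. Ambiguity is likewise coupled to disagreement: a message whose
second annotator deviates to another label draws its off-signal tokens
from that perceived class's vocabulary, so lax-tier examples contain
genuinely mixed wording rather than full-strength text of their true
class — disagreement in real annotation marks hard messages, not clean
ones. At `signal_strength = 1` there are no off-signal positions, so
fully separable corpora remain available for sanity checks.

What the generator does **not** emulate: real lexical diversity and
morphology, conversation threads, user/network structure, topic drift
over time, and per-annotator bias. Passing tests on synthetic corpora
therefore demonstrate the correctness and the qualitative behavior of the
pipeline (separable data are learned, permuted labels fall to the
analytic null, SVM tends to beat NB under correlated noise, agreement
statistics recover their configured values) — not the absolute
performance figures attainable on real Dutch tweets.

## Numerical choices and degenerate inputs

* Report rounding: two decimals, half away from zero (`round_half_up()`),
  matching the printed-table convention; base R's round-half-even would
  disagree on exact midpoints.
* Alpha with a single observed category raises an error (undefined), as
  does AUC with a single-class truth vector.
* Precision/recall with empty denominators return 0 with a warning.
* Naive Bayes zero-count likelihoods use epsilon 1e-10 (configurable).
* Vocabulary ties at the frequency cap break lexicographically (C
  locale via radix ordering), making the vocabulary deterministic.
* Stratified folds and all simulations are seeded; libsvm and the
  calibration glm are deterministic given the data.
* Learning-curve points whose subset lacks a second class are skipped
  with a warning.

## Problem sizes used by the test suite

The packaged tests and the acceptance script run the full battery at
reduced sizes chosen to keep the suite fast while leaving every
qualitative effect measurable: synthetic corpora of 400–1,500 messages
(10,000 for distributional recovery checks), vocabulary caps of 150–500
features, and 3–5-fold cross-validation; the 32-cell grid runs on a
1,200-message mid-noise corpus with 5 folds and a 500-feature cap. The
defaults of the exported functions remain the full-scale settings (10
folds, 15,000 features).

## Known limitations

* Retweet detection is prefix-based; quote-tweets are not removed.
* The rule scorer applies lexicon weights to any token, not only
  adjectives, since no part-of-speech tagger is in scope.
* The SVM probability calibration method and the one-vs-rest
  decomposition are implementation-defined choices; other calibrations
  would give slightly different threshold sweeps.
* The annotator model is exchangeable and its confusion model uniform by
  default; it cannot simultaneously match every published agreement
  statistic (e.g. it reproduces the stance agreement regime while its
  relevance agreement runs higher than observed).
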