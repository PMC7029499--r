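# vaxstance

Monitoring **negative stance towards vaccination** in short social-media
messages.

Public-health institutes track social media to detect vaccine hesitancy
early. Off-the-shelf sentiment analysis does poorly here because *stance*
— the author's position towards vaccination — is not the surface
sentiment of the words: an angry message can be pro-vaccination
(frustration with anti-vaccination arguments) and a polite one firmly
against. `vaxstance` implements the full surveillance pipeline for this
task, oriented at the class that matters for monitoring: messages with a
negative stance.

## What the package provides

* **Corpus filtering** — the three collection-stage rules (retweets by
  `"RT @"` prefix, messages with URLs, messages with off-topic blacklist
  words), with a per-query-term staged count report.
* **Agreement analysis** — percent agreement, Krippendorff's nominal
  alpha `α = 1 − D_o/D_e` over the coincidence matrix (tolerant of
  singly-annotated units and varying annotator pairs), and per-category
  mutual F-scores (F1 with one annotator as truth, symmetric under role
  exchange).
* **Harmonization** — doubly-coded messages resolve into reliability
  tiers: *strict* (both annotators agree), *lax* (disagreement resolved
  by a fixed category-preference order, Negative first), *one* (single
  annotator); at four labeling granularities (binary, irrelevance
  filter, polarity, polarity+sentiment) and four training-data variants
  (strict, +lax, +one, +lax+one).
* **Classifiers** — `stance_model()` fits binary word-n-gram models
  (top-15,000 document-frequency vocabulary, built per training fold):
  multinomial naive Bayes (smoothing 0.0, muted prior) or a linear SVM
  (C = 1.0, balanced class weights, one-vs-rest) with Platt-calibrated
  per-class probabilities, plus `predict_with_threshold()` to trade
  precision against recall on the Negative class.
* **Rule-based polarity scorer** — lexicon weights in [−1, 1] with
  intensity modifiers, product aggregation, and threshold calibration
  into Negative/Neutral/Positive.
* **Evaluation battery** — stratified cross-validation on the strict
  tier only (augmentation tiers never reach a test fold), Negative-class
  precision/recall/F1 and Mann–Whitney AUC, random baselines,
  precision-oriented (AND) and recall-oriented (OR) ensembles, threshold
  sweeps and learning curves; `run_grid()` enumerates all
  4 × 4 × 2 = 32 systems.
* **Synthetic corpus generator** — `generate_corpus()` emulates the
  study conditions of an annotated Dutch vaccination-tweet corpus
  (class proportions, 78% double annotation, agreement levels,
  collection artifacts, bursty ambiguous text), so the whole pipeline is
  testable without the original data.

## Worked example

```r
library(vaxstance)

## collection-stage filtering on a raw corpus with artifacts
raw <- generate_corpus(generator_config(n_tweets = 2000, seed = 42))
filter_corpus(raw$tweets)$report
#>  query_term before after_retweets after_urls after_blacklist
#>       Total   2000           1394        571             564

## an annotated corpus without collection artifacts
corpus <- generate_corpus(generator_config(
  n_tweets = 2000, seed = 42,
  artifact_rates = c(retweet = 0, url = 0, blacklist = 0)))

agreement_report(corpus$annotations)
#> Inter-annotator agreement
#>   relevance  percent agreement 0.90  alpha 0.74
#>   stance     percent agreement 0.60  alpha 0.41
#>     mutual F: Negative 0.51, Neutral 0.54, Not clear 0.42, Positive 0.71
#>   sentiment  percent agreement 0.56  alpha 0.42
#>   ...

inst <- harmonize(corpus$annotations, "polarity")
table(inst$tier)
#>    lax    one strict
#>    598    412    990

texts <- setNames(corpus$tweets$text, corpus$tweets$id)
ev <- cross_validate(inst, texts, variant = "strict+lax", algorithm = "svm",
                     n_folds = 5, seed = 1, max_features = 1000)
ev
#> Cross-validated stance evaluation [polarity | strict+lax | svm]
#>   Negative: precision 0.56  recall 0.85  F1 0.68  AUC 0.94  (n = 990 strict)

threshold_sweep(ev$prob, ev$truth, "Negative", grid = c(0.05, 0.25, 0.5, 0.75))
#>   threshold precision recall   f1
#> 1      0.05      0.52   0.92 0.66
#> 2      0.25      0.55   0.87 0.67
#> 3      0.50      0.56   0.85 0.68
#> 4      0.75      0.56   0.81 0.66
```

Reading the output: 990 of the doubly-annotated messages are *strict*
(identically coded by both annotators) and form the evaluation
population; lax messages only augment training. The cross-validated SVM
detects the Negative class at F1 0.68 on this mid-noise synthetic
corpus, and lowering the decision threshold raises recall (0.85 → 0.92)
at a modest precision cost — the trade-off a monitoring dashboard
operator steers.

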