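# Evaluation battery: metrics, AUC, cross-validation, baselines, ensembles,
# sweeps and learning curves.

test_that("binary metrics follow the precision/recall definitions", {
  cm <- confusion_table(c("Negative", "Negative", "Other", "Other"),
                        c("Negative", "Other", "Negative", "Other"))
  m <- binary_metrics(cm, "Negative")
  expect_equal(unname(m), c(0.5, 0.5, 0.5))
  perfect <- confusion_table(rep(c("Negative", "Other"), 5),
                             rep(c("Negative", "Other"), 5))
  expect_equal(unname(binary_metrics(perfect, "Negative")), c(1, 1, 1))
  # degenerate: no target predictions -> 0 with a warning
  none <- confusion_table(c("Negative", "Other"), c("Other", "Other"))
  expect_warning(m0 <- binary_metrics(none, "Negative"), "precision")
  expect_equal(unname(m0["precision"]), 0)
})

test_that("reported F1 is the harmonic mean of precision and recall", {
  set.seed(107)
  for (r in 1:20) {
    truth <- sample(c("Negative", "Other"), 50, replace = TRUE)
    pred <- sample(c("Negative", "Other"), 50, replace = TRUE)
    m <- suppressWarnings(binary_metrics(confusion_table(truth, pred), "Negative"))
    expect_equal(m[["f1"]], f1_score(m[["precision"]], m[["recall"]]),
                 tolerance = 1e-9)
  }
})

test_that("AUC is the Mann-Whitney statistic with ties at one half", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9), c(TRUE, TRUE, FALSE, FALSE)), 0)
  expect_equal(auc_score(c(0.5, 0.5), c(TRUE, FALSE)), 0.5)
  expect_error(auc_score(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
  set.seed(109)
  for (r in 1:100) {
    n <- sample(5:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    truth <- runif(n) < 0.4
    if (length(unique(truth)) < 2) next
    expect_equal(auc_score(scores, truth), auc_brute_force(scores, truth),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(113)
  scores <- runif(80)
  truth <- runif(80) < 0.3
  truth[1:2] <- c(TRUE, FALSE)
  ref <- as.numeric(pROC::auc(pROC::roc(response = truth, predictor = scores,
                                        quiet = TRUE, direction = "<")))
  expect_equal(auc_score(scores, truth), ref, tolerance = 1e-12)
})

test_that("ensembles implement conjunction and disjunction on Negative", {
  expect_equal(ensemble_labels("Negative", "Negative", "precision"), "Negative")
  expect_equal(ensemble_labels("Negative", "Negative", "recall"), "Negative")
  expect_equal(ensemble_labels("Negative", "Other", "precision"), "Other")
  expect_equal(ensemble_labels("Negative", "Other", "recall"), "Negative")
  expect_error(ensemble_labels(c("Negative", "Other"), "Negative", "recall"),
               "length mismatch")
  set.seed(127)
  a <- sample(c("Negative", "Other"), 100, replace = TRUE)
  b <- sample(c("Negative", "Other"), 100, replace = TRUE)
  n_prec <- sum(ensemble_labels(a, b, "precision") == "Negative")
  n_rec <- sum(ensemble_labels(a, b, "recall") == "Negative")
  expect_lte(n_prec, min(sum(a == "Negative"), sum(b == "Negative")))
  expect_gte(n_rec, max(sum(a == "Negative"), sum(b == "Negative")))
})

test_that("random baseline hits its analytic extremes", {
  truth <- c(rep(TRUE, 30), rep(FALSE, 70))
  all_in <- random_baseline(truth, rate = 1, repeats = 5, seed = 1)
  expect_equal(unname(all_in["recall"]), 1)
  expect_equal(unname(all_in["precision"]), 0.3)
  none <- random_baseline(truth, rate = 0, repeats = 5, seed = 1)
  expect_equal(unname(none["f1"]), 0)
})

test_that("threshold sweep covers the operating range with monotone recall", {
  toy <- separable_toy(10)
  m <- stance_model(toy$x, toy$y, algorithm = "svm")
  pr <- predict(m, toy$x)
  sw <- threshold_sweep(pr, toy$y, "Negative")
  expect_true(all(diff(sw$recall) <= 0))
  # perfectly separable: some threshold achieves precision = recall = 1
  expect_true(any(sw$precision == 1 & sw$recall == 1))
  # sweep F1 at its best is at least the default argmax F1
  cm <- confusion_table(toy$y, pr$label)
  expect_gte(max(sw$f1), binary_metrics(cm, "Negative")[["f1"]])
  # F1 at any point is the harmonic mean of its own precision and recall
  expect_equal(sw$f1, f1_score(sw$precision, sw$recall), tolerance = 1e-12)
})

test_that("cross-validation learns a separable corpus and guards test purity", {
  co <- clean_corpus(n = 520, seed = 131, signal_strength = 1,
                     single_annotation_rate = 0, agreement_rate = 1)
  inst <- harmonize(co$annotations, "binary")
  ev <- cross_validate(inst, texts_of(co), variant = "strict",
                       algorithm = "svm", n_folds = 4, seed = 1,
                       max_features = 400)
  expect_gt(ev$f1, 0.9)
  expect_equal(sum(ev$confusion), ev$n)
  expect_equal(ev$f1, f1_score(ev$precision, ev$recall), tolerance = 1e-9)
  expect_equal(nrow(ev$per_fold), 4)
  expect_output(print(ev), "Cross-validated")
})

test_that("cross-validation refuses classes rarer than the fold count", {
  co <- clean_corpus(n = 120, seed = 137)
  inst <- harmonize(co$annotations, "polarity_sentiment")
  expect_error(cross_validate(inst, texts_of(co), n_folds = 50,
                              max_features = 100),
               "stratification error")
})

test_that("augmentation tiers enter training but never testing", {
  co <- clean_corpus(n = 250, seed = 139)
  inst <- harmonize(co$annotations, "binary")
  ev_s <- cross_validate(inst, texts_of(co), variant = "strict",
                         algorithm = "nb", n_folds = 3, max_features = 200)
  ev_a <- cross_validate(inst, texts_of(co), variant = "strict+lax+one",
                         algorithm = "nb", n_folds = 3, max_features = 200)
  # the evaluated population is the strict tier in both cases
  expect_equal(ev_s$n, ev_a$n)
  expect_equal(sum(ev_a$confusion), sum(table(inst$tier)[["strict"]]))
})

test_that("the experiment grid enumerates every cell once", {
  co <- clean_corpus(n = 220, seed = 149)
  g <- run_grid(co$annotations, texts_of(co),
                schemes = c("binary", "polarity"),
                variants = c("strict", "strict+lax"),
                algorithms = c("nb", "svm"),
                n_folds = 3, max_features = 150)
  expect_equal(nrow(g), 2 * 2 * 2)
  expect_equal(anyDuplicated(g[c("scheme", "variant", "algorithm")]), 0)
  expect_length(attr(g, "reports"), 8)
})

test_that("the learning curve uses nested subsets and ends at the full pool", {
  co <- clean_corpus(n = 300, seed = 151, signal_strength = 0.9)
  inst <- harmonize(co$annotations, "binary")
  lc <- learning_curve(inst, texts_of(co), algorithm = "nb", n_points = 5,
                       seed = 2, max_features = 200)
  expect_true(all(diff(lc$n_train) > 0))
  expect_equal(lc$fraction[nrow(lc)], 1)

  # the 100% point equals a plain train/test evaluation on the same split
  lc1 <- learning_curve(inst, texts_of(co), algorithm = "nb", n_points = 1,
                        seed = 2, max_features = 200)
  expect_equal(lc1$f1, lc$f1[nrow(lc)], tolerance = 1e-12)
  expect_equal(lc1$auc, lc$auc[nrow(lc)], tolerance = 1e-12)
})

test_that("with strong signal more training data tends to help", {
  finals <- firsts <- numeric(0)
  for (sd in 1:3) {
    co <- clean_corpus(n = 260, seed = 160 + sd, signal_strength = 0.9)
    inst <- harmonize(co$annotations, "binary")
    lc <- learning_curve(inst, texts_of(co), algorithm = "svm", n_points = 4,
                         seed = sd, max_features = 200)
    firsts <- c(firsts, lc$f1[1])
    finals <- c(finals, lc$f1[nrow(lc)])
  }
  expect_gte(mean(finals), mean(firsts))
})
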