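# Evaluation battery: target-class precision/recall/F1 and AUC, stratified
# cross-validation over the strict tier with tier-augmented training data,
# random baselines, precision-/recall-oriented ensembles, threshold sweeps
# and learning curves.

#' Confusion table from labels
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param labels label universe (default: union, sorted).
#' @return contingency table (truth in rows, predictions in columns).
#' @export
confusion_table <- function(truth, predicted, labels = NULL) {
  stopifnot(length(truth) == length(predicted))
  if (is.null(labels)) labels <- sort(unique(c(truth, predicted)))
  table(truth = factor(truth, levels = labels),
        predicted = factor(predicted, levels = labels))
}

#' Precision, recall and F1 for one target class
#'
#' Binary metrics computed from a confusion table by collapsing all
#' non-target labels: precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R). Degenerate denominators yield 0 with a warning.
#'
#' @param confusion a [confusion_table()] (truth x predicted).
#' @param target target class name.
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @export
binary_metrics <- function(confusion, target = "Negative") {
  stopifnot(target %in% rownames(confusion), target %in% colnames(confusion))
  tp <- confusion[target, target]
  fp <- sum(confusion[, target]) - tp
  fn <- sum(confusion[target, ]) - tp
  if (tp + fp == 0) warning("no predictions of the target class; precision set to 0")
  if (tp + fn == 0) warning("no true instances of the target class; recall set to 0")
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' F1 from a precision/recall operating point
#'
#' Harmonic mean `2PR/(P+R)`; 0 when both are 0.
#'
#' @param precision,recall operating point.
#' @return F1 score.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0, 2 * precision * recall / (precision + recall))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly drawn positive
#' instance outranks a uniformly drawn negative one, ties counted one half.
#'
#' @param scores ranking scores (larger = more positive).
#' @param truth logical (TRUE = positive class) or labels with `target`.
#' @param target positive class name when `truth` is not logical.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, truth, target = "Negative") {
  if (!is.logical(truth)) truth <- truth == target
  stopifnot(length(scores) == length(truth))
  npos <- sum(truth)
  nneg <- sum(!truth)
  if (npos == 0 || nneg == 0) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[truth]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Ensemble of two binary Negative predictions
#'
#' The precision-oriented mode labels a message Negative iff both systems
#' did (conjunction); the recall-oriented mode iff at least one did
#' (disjunction).
#'
#' @param pred_a,pred_b label vectors of equal length.
#' @param mode `"precision"` or `"recall"`.
#' @param target the Negative label.
#' @param other label for non-target decisions.
#' @return character vector of ensemble labels.
#' @export
ensemble_labels <- function(pred_a, pred_b, mode = c("precision", "recall"),
                            target = "Negative", other = "Other") {
  mode <- match.arg(mode)
  if (length(pred_a) != length(pred_b)) {
    stop("prediction length mismatch: ", length(pred_a), " vs ", length(pred_b),
         call. = FALSE)
  }
  a <- pred_a == target
  b <- pred_b == target
  hit <- if (mode == "precision") a & b else a | b
  ifelse(hit, target, other)
}

#' Random baseline for the Negative class
#'
#' Each message is independently labeled Negative with probability `rate`
#' and given a uniform random ranking score; precision, recall, F1 and AUC
#' are averaged over `repeats` simulations.
#'
#' @param truth logical (TRUE = Negative) or label vector.
#' @param rate probability of a Negative prediction.
#' @param repeats number of simulations (>= 1).
#' @param seed RNG seed.
#' @param target Negative label when `truth` is not logical.
#' @return named means: `precision`, `recall`, `f1`, `auc`.
#' @export
random_baseline <- function(truth, rate, repeats = 1000, seed = 1,
                            target = "Negative") {
  if (!is.logical(truth)) truth <- truth == target
  check_rate(rate, "rate")
  stopifnot(repeats >= 1)
  set.seed(seed)
  n <- length(truth)
  npos <- sum(truth)
  out <- matrix(NA_real_, repeats, 4,
                dimnames = list(NULL, c("precision", "recall", "f1", "auc")))
  for (r in seq_len(repeats)) {
    pred <- stats::runif(n) < rate
    tp <- sum(pred & truth)
    fp <- sum(pred & !truth)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rc <- if (npos == 0) 0 else tp / npos
    out[r, 1:3] <- c(p, rc, f1_score(p, rc))
    out[r, 4] <- auc_score(stats::runif(n), truth)
  }
  colMeans(out)
}

#' Precision-recall sweep over decision thresholds
#'
#' One (precision, recall, F1) triple per grid threshold, predicting the
#' target class iff its probability is at least the threshold. Recall is
#' non-increasing in the threshold.
#'
#' @param predictions a [predict.stance_model()] result, or a numeric vector
#'   of target-class probabilities.
#' @param truth true labels.
#' @param target target class.
#' @param grid thresholds to sweep.
#' @return data.frame `threshold`, `precision`, `recall`, `f1`.
#' @export
threshold_sweep <- function(predictions, truth, target = "Negative",
                            grid = seq(0, 1, by = 0.02)) {
  prob <- if (inherits(predictions, "stance_predictions")) {
    predictions$prob[, target]
  } else as.numeric(predictions)
  stopifnot(length(prob) == length(truth))
  pos <- truth == target
  rows <- lapply(grid, function(th) {
    pred <- prob >= th
    tp <- sum(pred & pos); fp <- sum(pred & !pos); fn <- sum(!pred & pos)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    data.frame(threshold = th, precision = p, recall = r, f1 = f1_score(p, r))
  })
  do.call(rbind, rows)
}

# Seeded stratified fold assignment; errors when any class has fewer strict
# instances than folds.
stratified_folds <- function(labels, n_folds, seed) {
  tab <- table(labels)
  if (any(tab < n_folds)) {
    stop("stratification error: class '", names(tab)[which.min(tab)],
         "' has ", min(tab), " strict instances for ", n_folds, " folds",
         call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(tab)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  fold
}

#' Cross-validated evaluation of one experimental cell
#'
#' Ten-fold (by default) cross-validation on the strict tier, stratified by
#' label. In every fold the training data are the strict training split plus
#' the augmentation tiers selected by `variant` (lax and/or one); testing is
#' always on strict instances only, and augmentation tiers never appear in a
#' test fold (the tiers partition the tweets, which is asserted). The
#' n-gram vocabulary is rebuilt on each fold's training messages only.
#' Confusion counts are pooled over folds and the AUC is computed on the
#' pooled out-of-fold target-class probabilities.
#'
#' @param instances a [harmonize()] result (tiered labeled instances).
#' @param texts named character vector, tweet id -> text.
#' @param variant training-data variant (see [build_variant()]).
#' @param algorithm `"svm"` or `"nb"` (see [stance_model()]).
#' @param n_folds number of folds.
#' @param seed fold seed.
#' @param target target class for the binary metrics.
#' @param max_features vocabulary cap.
#' @param ... further arguments to [stance_model()].
#' @return object of class `stance_eval`: target-class precision, recall, F1
#'   and AUC, the pooled confusion table, per-fold metrics and the system
#'   identifier.
#' @export
cross_validate <- function(instances, texts, variant = "strict",
                           algorithm = c("svm", "nb"), n_folds = 10, seed = 1,
                           target = "Negative", max_features = 15000L, ...) {
  algorithm <- match.arg(algorithm)
  stopifnot(inherits(instances, "data.frame"),
            all(c("tweet_id", "label", "tier") %in% names(instances)),
            !is.null(names(texts)))
  strict <- instances[instances$tier == "strict", , drop = FALSE]
  aug <- build_variant(instances, variant)
  aug <- aug[aug$tier != "strict", , drop = FALSE]
  if (length(intersect(strict$tweet_id, aug$tweet_id)) > 0) {
    stop("tier partition violated: augmentation tweets overlap the strict tier",
         call. = FALSE)
  }
  missing_txt <- setdiff(c(strict$tweet_id, aug$tweet_id), names(texts))
  if (length(missing_txt)) {
    stop("missing text for tweet id(s): ", missing_txt[1], call. = FALSE)
  }
  tokens <- lapply(texts[unique(c(strict$tweet_id, aug$tweet_id))], tokenize)

  fold <- stratified_folds(strict$label, n_folds, seed)
  pooled_truth <- character(0)
  pooled_pred <- character(0)
  pooled_prob <- numeric(0)
  per_fold <- vector("list", n_folds)
  labels_all <- sort(unique(instances$label))

  for (f in seq_len(n_folds)) {
    test <- strict[fold == f, , drop = FALSE]
    train <- rbind(strict[fold != f, , drop = FALSE], aug)
    stopifnot(length(intersect(test$tweet_id, train$tweet_id)) == 0)  # test purity
    tr_tok <- tokens[train$tweet_id]
    vocab <- build_vocabulary(tr_tok, max_features = max_features)
    x_tr <- vectorize_corpus(tr_tok, vocab, ids = train$tweet_id)
    x_te <- vectorize_corpus(tokens[test$tweet_id], vocab, ids = test$tweet_id)
    model <- stance_model(x_tr, train$label, algorithm = algorithm, ...)
    pr <- stats::predict(model, x_te)
    prob_t <- if (target %in% model$classes) pr$prob[, target] else
      rep(0, nrow(test))
    pooled_truth <- c(pooled_truth, test$label)
    pooled_pred <- c(pooled_pred, pr$label)
    pooled_prob <- c(pooled_prob, prob_t)
    cm_f <- confusion_table(test$label, pr$label, labels = labels_all)
    mf <- suppressWarnings(binary_metrics(cm_f, target))
    per_fold[[f]] <- data.frame(fold = f, n_test = nrow(test),
                                precision = mf["precision"], recall = mf["recall"],
                                f1 = mf["f1"], row.names = NULL)
  }

  confusion <- confusion_table(pooled_truth, pooled_pred, labels = labels_all)
  metrics <- suppressWarnings(binary_metrics(confusion, target))
  auc <- auc_score(pooled_prob, pooled_truth, target)
  structure(list(
    system = list(scheme = attr(instances, "scheme"), variant = variant,
                  algorithm = algorithm, n_folds = n_folds, seed = seed,
                  target = target, max_features = max_features),
    precision = unname(metrics["precision"]), recall = unname(metrics["recall"]),
    f1 = unname(metrics["f1"]), auc = auc,
    confusion = confusion,
    prob = pooled_prob, truth = pooled_truth, predicted = pooled_pred,
    per_fold = do.call(rbind, per_fold),
    n = nrow(strict)
  ), class = "stance_eval")
}

#' @export
print.stance_eval <- function(x, ...) {
  cat(sprintf("Cross-validated stance evaluation [%s | %s | %s]\n",
              x$system$scheme %||% "?", x$system$variant, x$system$algorithm))
  cat(sprintf("  %s: precision %.2f  recall %.2f  F1 %.2f  AUC %.2f  (n = %d strict)\n",
              x$system$target, round_half_up(x$precision), round_half_up(x$recall),
              round_half_up(x$f1), round_half_up(x$auc), x$n))
  invisible(x)
}

#' Run the full experimental grid
#'
#' Every combination of labeling scheme (4), training-data variant (4) and
#' classifier (2): 32 cross-validated systems, each scored on detecting the
#' target class.
#'
#' @param records annotation data.frame.
#' @param texts named character vector, tweet id -> text.
#' @param schemes,variants,algorithms grid axes.
#' @param ... passed to [cross_validate()].
#' @return data.frame with one row per cell (`scheme`, `variant`,
#'   `algorithm`, `precision`, `recall`, `f1`, `auc`); the full
#'   `stance_eval` objects are attached as attribute `reports`.
#' @export
run_grid <- function(records, texts, schemes = SCHEME_NAMES,
                     variants = VARIANT_NAMES, algorithms = c("nb", "svm"),
                     ...) {
  reports <- list()
  rows <- list()
  for (sn in schemes) {
    inst <- harmonize(records, sn)
    for (vn in variants) {
      for (alg in algorithms) {
        ev <- cross_validate(inst, texts, variant = vn, algorithm = alg, ...)
        key <- paste(sn, vn, alg, sep = " | ")
        reports[[key]] <- ev
        rows[[key]] <- data.frame(scheme = sn, variant = vn, algorithm = alg,
                                  precision = ev$precision, recall = ev$recall,
                                  f1 = ev$f1, auc = ev$auc,
                                  stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "reports") <- reports
  out
}

#' Learning curve on nested training subsets
#'
#' Holds out a fixed stratified strict test split, then trains on nested
#' increasing subsets (10%, 20%, ..., 100% by default) of the remaining
#' training pool (strict training data plus the tiers in `pool_tiers`),
#' reporting target-class F1 and AUC per point. Subsets are nested under the
#' same seed. Points whose subset lacks a second class are skipped with a
#' warning.
#'
#' @param instances a [harmonize()] result.
#' @param texts named character vector, tweet id -> text.
#' @param algorithm classifier.
#' @param pool_tiers tiers included in the growing pool (default strict+lax).
#' @param n_points number of curve points.
#' @param test_fraction held-out strict fraction.
#' @param seed RNG seed for the split and the nesting order.
#' @param target target class.
#' @param max_features vocabulary cap.
#' @param ... further arguments to [stance_model()].
#' @return data.frame `fraction`, `n_train`, `f1`, `auc`.
#' @export
learning_curve <- function(instances, texts, algorithm = c("svm", "nb"),
                           pool_tiers = c("strict", "lax"), n_points = 10,
                           test_fraction = 0.1, seed = 1, target = "Negative",
                           max_features = 15000L, ...) {
  algorithm <- match.arg(algorithm)
  strict <- instances[instances$tier == "strict", , drop = FALSE]
  set.seed(seed)
  test_idx <- unlist(lapply(split(seq_len(nrow(strict)), strict$label), function(ix) {
    sample(ix, max(1L, round(length(ix) * test_fraction)))
  }), use.names = FALSE)
  test <- strict[test_idx, , drop = FALSE]
  pool <- rbind(strict[-test_idx, , drop = FALSE],
                instances[instances$tier %in% setdiff(pool_tiers, "strict"), ,
                          drop = FALSE])
  order_ix <- sample(nrow(pool))
  tokens <- lapply(texts[c(pool$tweet_id, test$tweet_id)], tokenize)
  fractions <- seq_len(n_points) / n_points
  rows <- list()
  prev_n <- 0L
  for (fr in fractions) {
    n_tr <- max(1L, ceiling(fr * nrow(pool)))
    sub <- pool[order_ix[seq_len(n_tr)], , drop = FALSE]
    stopifnot(n_tr >= prev_n)  # nestedness by construction
    prev_n <- n_tr
    if (length(unique(sub$label)) < 2L) {
      warning("learning-curve point at fraction ", fr,
              " skipped: fewer than two classes in the subset")
      next
    }
    tr_tok <- tokens[sub$tweet_id]
    vocab <- build_vocabulary(tr_tok, max_features = max_features)
    x_tr <- vectorize_corpus(tr_tok, vocab, ids = sub$tweet_id)
    x_te <- vectorize_corpus(tokens[test$tweet_id], vocab, ids = test$tweet_id)
    model <- stance_model(x_tr, sub$label, algorithm = algorithm, ...)
    pr <- stats::predict(model, x_te)
    cm <- confusion_table(test$label, pr$label,
                          labels = sort(unique(instances$label)))
    mf <- suppressWarnings(binary_metrics(cm, target))
    auc <- if (target %in% model$classes && length(unique(test$label == target)) == 2) {
      auc_score(pr$prob[, target], test$label, target)
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(fraction = fr, n_train = n_tr,
                                            f1 = unname(mf["f1"]), auc = auc)
  }
  do.call(rbind, rows)
}
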