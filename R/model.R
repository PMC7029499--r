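# Statistical stance classifiers: multinomial naive Bayes (implemented here)
# and a linear SVM (libsvm via e1071), both exposed through one fitting
# function returning a classed object with calibrated per-class
# probabilities. The settings mirror the study configuration: NB with
# smoothing 0.0 and a muted (uniform) fit prior; SVM with a linear kernel,
# C = 1.0 and balanced class weights.

#' Fit a stance classifier
#'
#' @param x binary feature matrix (dense or `dgCMatrix`), messages in rows.
#' @param y class labels (character or factor), one per row of `x`.
#' @param algorithm `"svm"` (linear support-vector machine, one-vs-rest, with
#'   Platt-style logistic calibration of the decision values) or `"nb"`
#'   (multinomial naive Bayes).
#' @param nb_smoothing additive smoothing for NB feature likelihoods. The
#'   default 0.0 follows the study configuration; zero-count likelihoods then
#'   substitute `nb_epsilon` so no log of zero is ever taken.
#' @param nb_uniform_prior mute the fitted class prior (uniform prior),
#'   countering class imbalance; default TRUE as in the study configuration.
#' @param nb_epsilon substitute for zero-count likelihoods when
#'   `nb_smoothing` is 0.
#' @param cost SVM misclassification cost C.
#' @param class_weight `"balanced"` scales each class's loss contribution by
#'   `total / (n_classes * class_count)`; `NULL` for unweighted.
#' @return object of class `stance_model`.
#' @export
stance_model <- function(x, y, algorithm = c("svm", "nb"),
                         nb_smoothing = 0, nb_uniform_prior = TRUE,
                         nb_epsilon = 1e-10,
                         cost = 1, class_weight = "balanced") {
  algorithm <- match.arg(algorithm)
  y <- as.character(y)
  if (nrow(x) != length(y)) {
    stop("dimension mismatch: nrow(x) = ", nrow(x), " but length(y) = ", length(y),
         call. = FALSE)
  }
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stop("training requires at least two distinct labels", call. = FALSE)
  }
  stopifnot(cost > 0, nb_smoothing >= 0)
  fit <- if (algorithm == "nb") {
    fit_multinomial_nb(x, y, classes, nb_smoothing, nb_uniform_prior, nb_epsilon)
  } else {
    fit_ovr_svm(x, y, classes, cost, class_weight)
  }
  structure(list(algorithm = algorithm, classes = classes,
                 features = colnames(x), n_train = nrow(x),
                 class_counts = table(factor(y, levels = classes)),
                 fit = fit,
                 settings = list(nb_smoothing = nb_smoothing,
                                 nb_uniform_prior = nb_uniform_prior,
                                 nb_epsilon = nb_epsilon, cost = cost,
                                 class_weight = class_weight)),
            class = "stance_model")
}

fit_multinomial_nb <- function(x, y, classes, alpha, uniform_prior, eps) {
  x <- as.matrix(x)
  counts <- rowsum(x, group = factor(y, levels = classes))  # classes x features
  v <- ncol(x)
  loglik <- matrix(NA_real_, nrow = length(classes), ncol = v,
                   dimnames = list(classes, colnames(x)))
  for (k in seq_along(classes)) {
    ck <- counts[k, ] + alpha
    tot <- sum(counts[k, ]) + alpha * v
    p <- ck / tot
    p[p <= 0] <- eps  # smoothing 0.0: never log(0)
    loglik[k, ] <- log(p)
  }
  logprior <- if (uniform_prior) {
    rep(-log(length(classes)), length(classes))
  } else {
    n <- as.numeric(table(factor(y, levels = classes)))
    log(n / sum(n))
  }
  list(loglik = loglik, logprior = stats::setNames(logprior, classes))
}

# One-vs-rest linear SVMs with per-class Platt calibration fitted on the
# training decision values. Balanced weights in each binary subproblem:
# n / (2 * n_positive) and n / (2 * n_rest).
fit_ovr_svm <- function(x, y, classes, cost, class_weight) {
  x <- as.matrix(x)
  n <- nrow(x)
  models <- vector("list", length(classes))
  names(models) <- classes
  for (cl in classes) {
    yb <- factor(ifelse(y == cl, "yes", "no"), levels = c("yes", "no"))
    wts <- if (identical(class_weight, "balanced")) {
      tb <- table(yb)
      c(yes = n / (2 * tb[["yes"]]), no = n / (2 * tb[["no"]]))
    } else NULL
    m <- e1071::svm(x, yb, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = wts, probability = FALSE)
    pr <- stats::predict(m, x, decision.values = TRUE)
    dvm <- attr(pr, "decision.values")
    flip <- !startsWith(colnames(dvm)[1], "yes")
    dv <- if (flip) -as.numeric(dvm[, 1]) else as.numeric(dvm[, 1])
    y01 <- as.integer(yb == "yes")
    cal <- platt_fit(dv, y01)
    models[[cl]] <- list(svm = m, calibration = cal, flip = flip)
  }
  list(models = models)
}

# Decision value oriented so that larger means "the class of interest".
decision_for_class <- function(m, x) {
  pr <- stats::predict(m, as.matrix(x), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # column name "A/B" means positive values favor level A
  flip <- !startsWith(colnames(dv)[1], "yes")
  d <- as.numeric(dv[, 1])
  if (flip) -d else d
}

platt_fit <- function(dv, y01) {
  cal <- suppressWarnings(
    try(stats::glm(y01 ~ dv, family = stats::binomial(),
                   control = list(maxit = 50)), silent = TRUE)
  )
  co <- if (inherits(cal, "try-error")) c(NA_real_, NA_real_) else stats::coef(cal)
  if (any(!is.finite(co))) {
    # degenerate (e.g. perfectly separated with extreme fit): fall back to a
    # fixed-slope sigmoid on standardized decision values
    s <- stats::sd(dv)
    if (!is.finite(s) || s == 0) s <- 1
    co <- c(0, 1 / s)
  }
  unname(co)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' @export
print.stance_model <- function(x, ...) {
  cat(sprintf("Stance classifier (%s)\n",
              if (x$algorithm == "svm") "linear SVM, one-vs-rest" else
                "multinomial naive Bayes"))
  cat(sprintf("  %d training messages, %d features, %d classes\n",
              x$n_train, length(x$features), length(x$classes)))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.stance_model <- function(object, ...) {
  print(object)
  cat("Training class counts:\n")
  print(object$class_counts)
  s <- object$settings
  if (object$algorithm == "svm") {
    cat(sprintf("Settings: C = %g, class weight = %s, Platt-calibrated probabilities\n",
                s$cost, s$class_weight %||% "none"))
  } else {
    cat(sprintf("Settings: smoothing = %g (epsilon %g for zero counts), %s prior\n",
                s$nb_smoothing, s$nb_epsilon,
                if (s$nb_uniform_prior) "uniform" else "fitted"))
  }
  invisible(object)
}

#' Per-class feature weights
#'
#' For the linear SVM, the hyperplane weight of each feature in each
#' one-vs-rest subproblem; for naive Bayes, the feature log-likelihoods per
#' class. Rows are classes, columns features.
#'
#' @param object a fitted [stance_model()].
#' @param ... unused.
#' @return numeric matrix (classes x features).
#' @export
coef.stance_model <- function(object, ...) {
  if (object$algorithm == "nb") return(object$fit$loglik)
  w <- t(vapply(object$classes, function(cl) {
    entry <- object$fit$models[[cl]]
    wv <- as.numeric(t(entry$svm$coefs) %*% entry$svm$SV)
    if (entry$flip) -wv else wv
  }, numeric(length(object$features))))
  dimnames(w) <- list(object$classes, object$features)
  w
}

#' Predict stance labels and per-class probabilities
#'
#' Returns per-class ranking scores, calibrated probabilities summing to one
#' across classes, and the argmax label for every message. Deterministic
#' given the fitted model.
#'
#' @param object a fitted [stance_model()].
#' @param x feature matrix over the model's vocabulary.
#' @param ... unused.
#' @return object of class `stance_predictions`: list with `classes`,
#'   `scores` (matrix), `prob` (matrix, rows sum to 1) and `label`.
#' @export
predict.stance_model <- function(object, x, ...) {
  if (is.null(object$fit)) stop("model is not fitted", call. = FALSE)
  if (ncol(x) != length(object$features)) {
    stop("dimension mismatch: model has ", length(object$features),
         " features but x has ", ncol(x), call. = FALSE)
  }
  x <- as.matrix(x)
  if (object$algorithm == "nb") {
    scores <- x %*% t(object$fit$loglik) +
      matrix(object$fit$logprior, nrow(x), length(object$classes), byrow = TRUE)
    # posterior via log-sum-exp
    mx <- apply(scores, 1, max)
    w <- exp(scores - mx)
    prob <- w / rowSums(w)
  } else {
    scores <- vapply(object$classes, function(cl) {
      decision_for_class(object$fit$models[[cl]]$svm, x)
    }, numeric(nrow(x)))
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
    raw <- vapply(seq_along(object$classes), function(k) {
      co <- object$fit$models[[object$classes[k]]]$calibration
      sigmoid(co[1] + co[2] * scores[, k])
    }, numeric(nrow(x)))
    if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1)
    prob <- raw / rowSums(raw)
  }
  colnames(scores) <- object$classes
  colnames(prob) <- object$classes
  label <- object$classes[max.col(prob, ties.method = "first")]
  structure(list(classes = object$classes, scores = scores, prob = prob,
                 label = label), class = "stance_predictions")
}

#' @export
print.stance_predictions <- function(x, ...) {
  cat(sprintf("Stance predictions for %d messages over %d classes\n",
              length(x$label), length(x$classes)))
  print(table(x$label))
  invisible(x)
}

#' Threshold-overridden binary decision
#'
#' Labels a message as the target class iff its calibrated probability for
#' that class is at least `threshold`, and `"Other"` otherwise. Threshold 0
#' labels everything as the target; a threshold above 1 labels nothing.
#' Raising the threshold never increases recall.
#'
#' @param predictions a [predict.stance_model()] result.
#' @param target target class (default `"Negative"`).
#' @param threshold probability threshold.
#' @param other label used for non-target decisions.
#' @return character vector of labels.
#' @export
predict_with_threshold <- function(predictions, target = "Negative", threshold = 0.5,
                                   other = "Other") {
  stopifnot(inherits(predictions, "stance_predictions"))
  if (!target %in% predictions$classes) {
    stop("target class '", target, "' is not known to the model", call. = FALSE)
  }
  ifelse(predictions$prob[, target] >= threshold, target, other)
}
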