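# Inter-annotator agreement: percent agreement, Krippendorff's nominal alpha
# (tolerating singly-annotated units and varying annotator pairs), and
# per-category mutual F-scores.

# Values of one categorization by unit. Sub-category values (subject, stance,
# sentiment) are absent for Irrelevant tweets; by default they stay missing
# for agreement purposes. `absent_label` optionally substitutes a label (e.g.
# "Irrelevant") for those structurally absent values instead.
categorization_values <- function(records, categorization, absent_label = NULL) {
  categorization <- match.arg(categorization, CATEGORIZATIONS)
  stopifnot(is.data.frame(records),
            all(c("tweet_id", "annotator_id", categorization) %in% names(records)))
  vals <- records[[categorization]]
  if (!is.null(absent_label) && categorization != "relevance") {
    structural <- is.na(vals) & records$relevance == "Irrelevant"
    vals[structural] <- absent_label
  }
  keep <- !is.na(vals)
  data.frame(tweet_id = records$tweet_id[keep],
             annotator_id = records$annotator_id[keep],
             value = vals[keep], stringsAsFactors = FALSE)
}

# First two annotators (by sorted annotator id) per doubly-coded unit, as a
# two-column value matrix. Used by percent agreement and mutual F.
annotator_pairs <- function(records, categorization, absent_label = NULL) {
  v <- categorization_values(records, categorization, absent_label)
  if (nrow(v) == 0) return(data.frame(a = character(0), b = character(0)))
  v <- v[order(v$tweet_id, v$annotator_id, method = "radix"), ]
  sp <- split(v$value, v$tweet_id)
  sp <- sp[lengths(sp) >= 2L]
  data.frame(a = vapply(sp, `[`, character(1), 1L),
             b = vapply(sp, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Percent agreement on a categorization
#'
#' Fraction of doubly-annotated units on which the two annotators assigned an
#' identical label. Units where either annotator's value is absent are
#' excluded.
#'
#' @param records annotation data.frame (`tweet_id`, `annotator_id`,
#'   `relevance`, `subject`, `stance`, `sentiment`).
#' @param categorization one of `"relevance"`, `"subject"`, `"stance"`,
#'   `"sentiment"`.
#' @param absent_label optional label substituted for structurally absent
#'   sub-category values of Irrelevant tweets (default: treated as missing).
#' @return fraction in \[0, 1\].
#' @export
percent_agreement <- function(records, categorization, absent_label = NULL) {
  p <- annotator_pairs(records, categorization, absent_label)
  if (nrow(p) == 0) {
    stop("no doubly annotated units with '", categorization, "' present for both annotators",
         call. = FALSE)
  }
  mean(p$a == p$b)
}

#' Krippendorff's alpha (nominal) on a categorization
#'
#' Chance-corrected agreement, `1 - Do/De`, computed from the coincidence
#' matrix over all units with at least two values. Singly-annotated units
#' contribute nothing; different annotator pairs across units are handled
#' natively. Units with more than two annotators enter with all their
#' pairable values.
#'
#' @inheritParams percent_agreement
#' @return alpha in \[-1, 1\] (up to floating error).
#' @export
krippendorff_alpha <- function(records, categorization, absent_label = NULL) {
  v <- categorization_values(records, categorization, absent_label)
  sp <- split(v$value, v$tweet_id)
  sp <- sp[lengths(sp) >= 2L]
  if (length(sp) == 0) {
    stop("no units with at least two pairable '", categorization, "' values",
         call. = FALSE)
  }
  labels <- sort(unique(unlist(sp, use.names = FALSE)))
  L <- length(labels)
  o <- matrix(0, L, L, dimnames = list(labels, labels))
  for (vals in sp) {
    m <- length(vals)
    tab <- table(factor(vals, levels = labels))
    cnt <- as.numeric(tab)
    # ordered pairs within the unit, each weighted 1/(m-1)
    pair <- (outer(cnt, cnt) - diag(cnt, nrow = L)) / (m - 1)
    o <- o + pair
  }
  n <- sum(o)
  nc <- rowSums(o)
  d_obs <- (n - sum(diag(o))) / n
  d_exp <- (n^2 - sum(nc^2)) / (n * (n - 1))
  if (d_exp <= 0) {
    stop("Krippendorff's alpha undefined: only one category observed", call. = FALSE)
  }
  1 - d_obs / d_exp
}

#' Mutual F-scores per category
#'
#' For each category of a categorization, the F1-score over doubly-annotated
#' units with one annotator treated as ground truth and the other as
#' prediction, a unit counting as positive iff the annotator assigned that
#' category. F1 is symmetric under exchanging the two roles (true positives
#' are fixed while false positives and false negatives swap), which is
#' asserted. Categories never assigned by either annotator are absent from
#' the result rather than reported as 0.
#'
#' @inheritParams percent_agreement
#' @return named numeric vector of F-scores, one per observed category.
#' @export
mutual_f <- function(records, categorization, absent_label = NULL) {
  p <- annotator_pairs(records, categorization, absent_label)
  if (nrow(p) == 0) {
    stop("no doubly annotated units with '", categorization, "' present for both annotators",
         call. = FALSE)
  }
  cats <- sort(unique(c(p$a, p$b)))
  f_one <- function(truth, pred, cat) {
    tp <- sum(truth == cat & pred == cat)
    fp <- sum(truth != cat & pred == cat)
    fn <- sum(truth == cat & pred != cat)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  fw <- vapply(cats, function(cc) f_one(p$a, p$b, cc), numeric(1))
  bw <- vapply(cats, function(cc) f_one(p$b, p$a, cc), numeric(1))
  stopifnot(all(abs(fw - bw) < 1e-12))
  stats::setNames(fw, cats)
}

#' Merge categories of a categorization
#'
#' Generic relabeling used, e.g., to merge frequently confused stance
#' categories (Neutral and Not clear) before re-computing agreement.
#'
#' @param records annotation data.frame.
#' @param categorization categorization to relabel.
#' @param merge character vector of categories to merge.
#' @param into replacement label.
#' @return records with the categories merged.
#' @export
merge_categories <- function(records, categorization, merge, into = merge[1]) {
  categorization <- match.arg(categorization, CATEGORIZATIONS)
  v <- records[[categorization]]
  records[[categorization]] <- ifelse(!is.na(v) & v %in% merge, into, v)
  records
}

#' Agreement report over all four categorizations
#'
#' Percent agreement, Krippendorff's alpha and per-category mutual F-scores
#' for relevance, subject, stance and sentiment.
#'
#' @inheritParams percent_agreement
#' @return object of class `agreement_report`.
#' @export
agreement_report <- function(records, absent_label = NULL) {
  per_cat <- lapply(CATEGORIZATIONS, function(cc) {
    list(
      percent = tryCatch(percent_agreement(records, cc, absent_label),
                         error = function(e) NA_real_),
      alpha = tryCatch(krippendorff_alpha(records, cc, absent_label),
                       error = function(e) NA_real_),
      mutual_f = tryCatch(mutual_f(records, cc, absent_label),
                          error = function(e) stats::setNames(numeric(0), character(0)))
    )
  })
  names(per_cat) <- CATEGORIZATIONS
  structure(per_cat, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Inter-annotator agreement\n")
  for (cc in names(x)) {
    e <- x[[cc]]
    cat(sprintf("  %-10s percent agreement %s  alpha %s\n", cc,
                formatC(round_half_up(e$percent, 2), format = "f", digits = 2),
                formatC(round_half_up(e$alpha, 2), format = "f", digits = 2)))
    if (length(e$mutual_f)) {
      mf <- round_half_up(e$mutual_f, 2)
      cat("    mutual F:",
          paste(sprintf("%s %.2f", names(mf), mf), collapse = ", "), "\n")
    }
  }
  invisible(x)
}
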