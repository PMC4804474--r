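#' Confusion counts from true and predicted classes
#'
#' Tallies true/false positives and negatives. Classes use the package's
#' convention: levels `"N"` (negative) and `"P"` (positive).
#'
#' @param truth,estimate Vectors (factor or character) of classes in
#'   `c("N", "P")`, equal length.
#' @return A one-row tibble with integer columns `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(truth, estimate) {
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have equal length.")
  }
  bad <- setdiff(unique(c(truth, estimate)), c("N", "P"))
  if (length(bad)) {
    abort(sprintf("classes must be \"N\" or \"P\"; found %s.",
                  paste(dQuote(bad), collapse = ", ")))
  }
  tibble(tp = sum(truth == "P" & estimate == "P"),
         fn = sum(truth == "P" & estimate == "N"),
         tn = sum(truth == "N" & estimate == "N"),
         fp = sum(truth == "N" & estimate == "P"))
}

#' Sensitivity, specificity, accuracy and balanced accuracy
#'
#' Derives the standard binary performance measures from confusion counts:
#' `sn = tp / (tp + fn)`, `sp = tn / (tn + fp)`,
#' `acc = (tp + tn) / (tp + fn + tn + fp)` and the balanced accuracy
#' `avc = (sn + sp) / 2`, which ranks a degenerate majority-class predictor
#' at 0.5 regardless of class imbalance (e.g. predicting every one of 100
#' positives and 10,000 negatives as negative gives `acc = 0.9901` but
#' `avc = 0.5`).
#'
#' @param counts A data frame with columns `tp`, `fn`, `tn`, `fp`
#'   (one or more rows), as returned by [confusion_counts()].
#' @return A tibble with columns `sn`, `sp`, `acc`, `avc`, one row per row
#'   of `counts`.
#' @examples
#' classification_metrics(data.frame(tp = 0, fn = 100, tn = 10000, fp = 0))
#' @export
classification_metrics <- function(counts) {
  need <- c("tp", "fn", "tn", "fp")
  if (!all(need %in% names(counts))) {
    abort("`counts` must have columns tp, fn, tn, fp.")
  }
  p <- counts$tp + counts$fn
  n <- counts$tn + counts$fp
  if (any(p < 1) || any(n < 1)) {
    abort("both classes must be present (tp + fn >= 1 and tn + fp >= 1).",
          class = "mctwo_absent_class")
  }
  sn <- counts$tp / p
  sp <- counts$tn / n
  tibble(sn = sn, sp = sp, acc = (counts$tp + counts$tn) / (p + n),
         avc = (sn + sp) / 2)
}

#' Accuracy-complexity evaluation index
#'
#' `EI = acc - p / 100`: trades classification accuracy (fraction scale)
#' against the number `p` of features in the model; each additional feature
#' costs exactly 0.01.
#'
#' @param acc Accuracy in \[0, 1\] (vectorised).
#' @param p Number of selected features, `p >= 0` (vectorised).
#' @return `acc - p / 100`.
#' @export
ei <- function(acc, p) {
  if (any(acc < 0 | acc > 1)) abort("`acc` must be in [0, 1] (fraction scale).")
  if (any(p < 0)) abort("`p` must be non-negative.")
  acc - p / 100
}

#' Win/tie/loss comparison triplet
#'
#' Counts, over a common set of datasets, how often selector `a` scores
#' strictly higher than, equal to, and strictly lower than selector `b`.
#' If both vectors are named they are matched by name.
#'
#' @param a,b Numeric score vectors (e.g. per-dataset maximal accuracy),
#'   equal length; if named, names must coincide as sets.
#' @param tol Non-negative tie tolerance; scores within `tol` count as a
#'   tie. Default 0 (exact comparison).
#' @return A one-row tibble with integer columns `win`, `tie`, `loss`
#'   (`win + tie + loss == length(a)`).
#' @examples
#' comparison_triplet(c(0.9, 0.8, 0.7), c(0.9, 0.7, 0.8))
#' @export
comparison_triplet <- function(a, b, tol = 0) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      abort("`a` and `b` must cover the same datasets (names differ).")
    }
    b <- b[names(a)]
  }
  d <- a - b
  tibble(win = sum(d > tol), tie = sum(abs(d) <= tol), loss = sum(d < -tol))
}

#' Paired t-test between two aligned score vectors or CV reports
#'
#' Computes the paired t statistic over matched scores (fold-by-fold when
#' given two [cv_report][internal_cv] objects, which are aligned on
#' run/fold/classifier). Degenerate difference vectors follow a documented
#' convention: all-zero differences give `statistic = 0, p = 1`; a constant
#' non-zero difference (zero variance) gives `statistic = +/-Inf, p = 0`.
#'
#' @param a,b Numeric vectors of equal length, or two `cv_report` objects
#'   with identical run/fold/classifier structure.
#' @param metric Metric column to compare when `a` and `b` are reports
#'   (default `"acc"`).
#' @return A one-row tibble: `statistic`, `df`, `p.value`, `mean_diff`, and
#'   logical significance flags `sig_95`, `sig_99` at the 0.95 and 0.99
#'   confidence levels.
#' @export
paired_comparison <- function(a, b, metric = "acc") {
  if (inherits(a, "cv_report") && inherits(b, "cv_report")) {
    keys <- c("run", "fold", "classifier")
    ra <- dplyr::arrange(a$records, .data$run, .data$fold, .data$classifier)
    rb <- dplyr::arrange(b$records, .data$run, .data$fold, .data$classifier)
    if (!identical(ra[keys], rb[keys])) {
      abort("the two reports do not share the same run/fold/classifier cells.")
    }
    a <- ra[[metric]]
    b <- rb[[metric]]
  }
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) < 2) abort("at least two paired scores are required.")
  d <- a - b
  n <- length(d)
  md <- mean(d)
  s <- sd(d)
  if (s == 0) {
    stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    stat <- md / (s / sqrt(n))
    p <- 2 * pt(-abs(stat), df = n - 1)
  }
  tibble(statistic = stat, df = n - 1, p.value = p, mean_diff = md,
         sig_95 = p < 0.05, sig_99 = p < 0.01)
}
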