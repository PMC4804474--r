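# Cross-validation harnesses. Feature selection always runs inside the
# training portion of each fold; the held-out fold only ever sees trained
# models. Folds are stratified by class. When a selector returns no
# features (possible on null data), the fold's model predicts the
# training-set majority class (ties to "N") — keeping the harness defined
# on pure-noise datasets, where held-out accuracy should then match the
# majority-class rate.

#' Selector factories for the cross-validation harness
#'
#' A *selector* is any `function(data, label)` taking a tidy frame and the
#' label column name as a string and returning a character vector of chosen
#' feature ids (possibly empty). These factories wrap the package's
#' selectors with fixed parameters:
#' `selector_mctwo()` and `selector_mcone()` run the two-step / filter-only
#' selector (an empty MIC screen yields an empty selection rather than an
#' error); `selector_rank(method, k)` takes the top-`k` features of a
#' filter ranking; `selector_all()` performs no selection.
#'
#' @param r,alpha,clumps,max_stale See [mctwo()].
#' @param method,k See [rank_features()] and [top_k()].
#' @return A selector function.
#' @name selectors
NULL

#' @rdname selectors
#' @export
selector_mctwo <- function(r = 0.2, max_stale = 5, alpha = 0.6, clumps = 15) {
  function(data, label) {
    fit <- tryCatch(
      rlang::inject(mctwo(data, !!rlang::sym(label), r = r,
                          max_stale = max_stale, alpha = alpha,
                          clumps = clumps)),
      mctwo_empty_selection = function(e) NULL)
    if (is.null(fit)) character(0) else fit$selected
  }
}

#' @rdname selectors
#' @export
selector_mcone <- function(r = 0.2, alpha = 0.6, clumps = 15) {
  function(data, label) {
    rlang::inject(mcone(data, !!rlang::sym(label), r = r, alpha = alpha,
                        clumps = clumps))$selected
  }
}

#' @rdname selectors
#' @export
selector_rank <- function(method = "trank", k = 5) {
  function(data, label) {
    rk <- rlang::inject(rank_features(data, !!rlang::sym(label),
                                      method = method))
    top_k(rk, min(k, nrow(rk)))
  }
}

#' @rdname selectors
#' @export
selector_all <- function() {
  function(data, label) {
    is_num <- vapply(data, is.numeric, logical(1))
    setdiff(names(data)[is_num], label)
  }
}

stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assign
}

majority_class <- function(y) {
  tab <- table(y)
  if (tab[["P"]] > tab[["N"]]) "P" else "N"  # tie -> N
}

cv_run <- function(data, d, lab, selector, classifiers, folds, run,
                   selector_name = NULL) {
  fold_of <- stratified_folds(d$y, folds)
  recs <- vector("list", folds * length(classifiers))
  ri <- 0L
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    sel <- selector(data[tr, , drop = FALSE], lab)
    sel <- as.character(sel)
    unknown <- setdiff(sel, d$feature_ids)
    if (length(unknown)) {
      abort(sprintf("selector returned unknown feature id(s): %s.",
                    paste(dQuote(head(unknown, 5)), collapse = ", ")))
    }
    for (m in classifiers) {
      pred <- if (length(sel) == 0) {
        factor(rep(majority_class(d$y[tr]), length(te)),
               levels = c("N", "P"))
      } else {
        predict_matrix(m, d$x[tr, sel, drop = FALSE], d$y[tr],
                       d$x[te, sel, drop = FALSE])
      }
      cc <- confusion_counts(d$y[te], pred)
      mt <- classification_metrics(cc)
      ri <- ri + 1L
      recs[[ri]] <- dplyr::bind_cols(
        tibble(run = run, fold = f, classifier = m,
               n_features = length(sel)),
        cc, mt)
    }
  }
  out <- dplyr::bind_rows(recs)
  if (!is.null(selector_name)) {
    out <- dplyr::bind_cols(tibble(selector = selector_name,
                                   .rows = nrow(out)), out)
  }
  out
}

summarize_cv <- function(records) {
  keys <- intersect(c("selector", "classifier"), names(records))
  pooled <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "run")))) |>
    dplyr::summarise(tp = sum(.data$tp), fn = sum(.data$fn),
                     tn = sum(.data$tn), fp = sum(.data$fp),
                     n_features = mean(.data$n_features),
                     .groups = "drop")
  pooled <- dplyr::bind_cols(pooled, classification_metrics(pooled))
  pooled |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean_sn = mean(.data$sn), mean_sp = mean(.data$sp),
      mean_acc = mean(.data$acc), sd_acc = sd(.data$acc),
      mean_avc = mean(.data$avc), mean_n_features = mean(.data$n_features),
      .groups = "drop")
}

new_cv_report <- function(records, scheme, seeds) {
  structure(list(records = records, summary = summarize_cv(records),
                 scheme = scheme, seeds = seeds),
            class = "cv_report")
}

#' Internal cross-validation of a feature selector
#'
#' Repeated stratified k-fold cross-validation: for each of `runs`
#' repetitions (seeded `seed, seed + 1, ...`), samples are split into
#' `folds` class-stratified folds; within every fold the full selector is
#' re-run on the training portion only, each classifier is trained on the
#' training portion restricted to the selected features, and the held-out
#' fold is scored. Per-run metrics pool the confusion counts across the
#' run's folds; the summary averages those pooled metrics over runs.
#'
#' @inheritParams mic_relevance
#' @param selector A selector function (see [selectors]).
#' @param classifiers Character vector from
#'   `c("NN", "SVM", "NBayes", "DTree")`.
#' @param runs Number of repetitions. Default 30.
#' @param folds Number of folds. Default 5. Each class must have at least
#'   `folds` samples so every fold contains both classes.
#' @param seed Base seed; run `i` uses `seed + i - 1`.
#' @return A `cv_report`: list with `records` (one row per
#'   run x fold x classifier: confusion counts, `sn`, `sp`, `acc`, `avc`,
#'   `n_features`), `summary` (per classifier), `scheme` and `seeds`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' d <- synth_data(n_pos = 15, n_neg = 15, n_noise = 10, seed = 1)
#' internal_cv(d, label, selector_rank("trank", 2), "NN", runs = 2, folds = 3)
#' @export
internal_cv <- function(data, label, selector = selector_mctwo(),
                        classifiers = c("NN", "SVM", "NBayes", "DTree"),
                        runs = 30, folds = 5, seed = 1, positive = NULL) {
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  lab <- as_name(enquo(label))
  d <- as_fs(data, {{ label }}, positive = positive)
  check_folds(d$y, folds)
  seeds <- seed + seq_len(runs) - 1
  records <- dplyr::bind_rows(lapply(seq_len(runs), function(run) {
    with_seed(seeds[run],
              cv_run(data, d, lab, selector, classifiers, folds, run))
  }))
  new_cv_report(records, sprintf("internal-%dfold-%druns", folds, runs),
                seeds)
}

#' External cross-validation comparing several selectors
#'
#' Same fold structure as [internal_cv()], but several selectors are
#' evaluated on identical folds (selection still re-run inside every
#' training fold). The per-fold records are the raw material for box-plot
#' comparisons and for checking selection bias: on data whose labels are
#' independent of all features, held-out accuracy should match the
#' majority-class rate.
#'
#' @inheritParams internal_cv
#' @param selectors Named list of selector functions.
#' @param runs Number of repetitions. Default 10.
#' @return A `cv_report` whose `records` carry a `selector` column.
#' @export
external_cv <- function(data, label, selectors = list(McTwo = selector_mctwo()),
                        classifiers = "NN", runs = 10, folds = 5, seed = 1,
                        positive = NULL) {
  classifiers <- match.arg(classifiers,
                           c("NN", "SVM", "NBayes", "DTree"),
                           several.ok = TRUE)
  if (!is.list(selectors) || is.null(names(selectors)) ||
      any(names(selectors) == "")) {
    abort("`selectors` must be a named list of selector functions.")
  }
  lab <- as_name(enquo(label))
  d <- as_fs(data, {{ label }}, positive = positive)
  check_folds(d$y, folds)
  seeds <- seed + seq_len(runs) - 1
  records <- dplyr::bind_rows(lapply(seq_len(runs), function(run) {
    dplyr::bind_rows(lapply(names(selectors), function(sn) {
      # same seed per run for every selector: identical fold assignment
      with_seed(seeds[run],
                cv_run(data, d, lab, selectors[[sn]], classifiers, folds,
                       run, selector_name = sn))
    }))
  }))
  new_cv_report(records, sprintf("external-%dfold-%druns", folds, runs),
                seeds)
}

check_folds <- function(y, folds) {
  if (!is.numeric(folds) || folds < 2) abort("`folds` must be at least 2.")
  if (min(table(y)) < folds) {
    abort(sprintf(
      "each class needs at least `folds` = %d samples for stratified folds (smallest class has %d).",
      folds, min(table(y))))
  }
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cross-validation report (%s), %d records\n", x$scheme,
              nrow(x$records)))
  print(x$summary, ...)
  invisible(x)
}

#' Maximal accuracy across classifiers
#'
#' The best mean cross-validated accuracy over the evaluated classifiers —
#' the score a practitioner deploying the best available model would see —
#' per selector when the report compares several.
#'
#' @param report A `cv_report`.
#' @return A tibble with the best classifier and its mean accuracy
#'   (`macc`), one row per selector (or a single row).
#' @export
macc <- function(report) {
  if (!inherits(report, "cv_report")) abort("`report` must be a cv_report.")
  keys <- intersect("selector", names(report$summary))
  report$summary |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::slice_max(.data$mean_acc, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(keys), best_classifier = "classifier",
                  macc = "mean_acc")
}
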