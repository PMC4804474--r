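# Step two: best-first search over the McOne candidates, scored by the
# leave-one-out balanced accuracy of a 1-nearest-neighbour classifier.

# 1-NN prediction rules (shared with the classifier adapters):
#   * Euclidean distance over the selected feature columns, no rescaling
#     (expression matrices arrive on a common normalised scale);
#   * distance ties are broken in favour of the smaller training index;
#   * if every training sample is equidistant from the query (no usable
#     signal, e.g. constant features), the prediction is "N" — the
#     degenerate all-negative classifier, which scores BAcc = 1/2.
loo_bacc_impl <- function(x, y, cols) {
  m <- x[, cols, drop = FALSE]
  D <- as.matrix(dist(m))
  s <- nrow(D)
  pred <- character(s)
  for (i in seq_len(s)) {
    di <- D[i, -i]
    if (max(di) - min(di) <= 1e-12 * (1 + max(di))) {
      pred[i] <- "N"
    } else {
      j <- which.min(di)  # first minimum = smallest index
      pred[i] <- as.character(y[-i][j])
    }
  }
  tp <- sum(pred == "P" & y == "P")
  tn <- sum(pred == "N" & y == "N")
  (tp / sum(y == "P") + tn / sum(y == "N")) / 2
}

#' Leave-one-out balanced accuracy of a 1-NN classifier
#'
#' Scores a feature subset by predicting each sample's class as the class of
#' its nearest neighbour (Euclidean distance over the subset's columns,
#' `k = 1`) among all other samples, then returning
#' `(sensitivity + specificity) / 2` of the pooled predictions. This is the
#' optimisation objective of the wrapper stage: unlike the overall accuracy
#' it ranks a degenerate majority-class predictor at 0.5 on imbalanced data.
#'
#' @inheritParams mic_relevance
#' @param features Character vector of feature column names (non-empty, no
#'   duplicates, all present in `data`).
#' @return A single number in \[0, 1\].
#' @examples
#' d <- synth_data(n_pos = 15, n_neg = 15, n_noise = 3, delta = 4, seed = 1)
#' loo_bacc(d, label, c("inf1", "inf2"))
#' @export
loo_bacc <- function(data, label, features, positive = NULL) {
  d <- as_fs(data, {{ label }}, positive = positive)
  features <- check_subset(d, features)
  loo_bacc_impl(d$x, d$y, features)
}

# Best-first search over subsets of `cand` (feature ids, most relevant
# first). Open list starts from all singletons; the best open node (highest
# score, then smaller subset, then lexicographically earlier id string) is
# expanded by adding each unused candidate. Terminates after `max_stale`
# consecutive expansions that fail to improve the best score (Inf = full
# exploration of the candidate power set).
best_first_impl <- function(x, y, cand, max_stale) {
  eps <- 1e-9
  score_of <- function(cols) loo_bacc_impl(x, y, cols)
  key_of <- function(cols) {
    paste(sort(cols, method = "radix"), collapse = "\x1f")  # locale-free
  }

  visited <- new.env(parent = emptyenv(), hash = TRUE)
  open_keys <- character(0)
  open_sets <- list()
  open_scores <- numeric(0)
  trail_sets <- list()
  trail_scores <- numeric(0)
  n_eval <- 0L

  better_tie <- function(cols, score, best_cols, best_score) {
    # is (cols, score) preferred over the incumbent under the tie rules?
    if (score > best_score + eps) return(TRUE)
    if (score < best_score - eps) return(FALSE)
    if (length(cols) != length(best_cols)) {
      return(length(cols) < length(best_cols))
    }
    key_of(cols) < key_of(best_cols)
  }

  push <- function(cols) {
    k <- key_of(cols)
    if (!is.null(visited[[k]])) return(NULL)
    sc <- score_of(cols)
    n_eval <<- n_eval + 1L
    visited[[k]] <- sc
    open_keys[[length(open_keys) + 1]] <<- k
    open_sets[[length(open_sets) + 1]] <<- cols
    open_scores[[length(open_scores) + 1]] <<- sc
    trail_sets[[length(trail_sets) + 1]] <<- cols
    trail_scores[[length(trail_scores) + 1]] <<- sc
    sc
  }

  best_cols <- NULL
  best_score <- -Inf
  for (f in cand) {
    sc <- push(f)
    if (better_tie(f, sc, best_cols %||% character(0), best_score)) {
      best_cols <- f
      best_score <- sc
    }
  }

  stale <- 0L
  while (length(open_keys) > 0 && stale < max_stale) {
    # best open node: max score, then smaller subset, then lexicographic key
    sizes <- lengths(open_sets)
    o <- order(-open_scores, sizes, open_keys)[1]
    node <- open_sets[[o]]
    open_keys <- open_keys[-o]
    open_sets <- open_sets[-o]
    open_scores <- open_scores[-o]

    improved <- FALSE
    for (f in setdiff(cand, node)) {
      child <- c(node, f)
      sc <- push(child)
      if (is.null(sc)) next
      if (sc > best_score + eps) {
        best_cols <- child
        best_score <- sc
        improved <- TRUE
      } else if (better_tie(child, sc, best_cols, best_score)) {
        best_cols <- child
        best_score <- sc
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }

  trail <- tibble(
    step = seq_along(trail_sets),
    features = lapply(trail_sets, function(s) {
      sort(unname(s), method = "radix")
    }),
    size = lengths(trail_sets),
    bacc = unlist(trail_scores)
  )
  list(selected = cand[cand %in% best_cols],  # McOne relevance order
       objective = best_score,
       trail = trail,
       n_evaluations = n_eval)
}

#' Best-first subset search scored by LOO balanced accuracy
#'
#' Searches subsets of `candidates` for the highest [loo_bacc()]. The open
#' list is seeded with every single-feature subset; at each step the
#' best-scoring open subset is expanded by adding each unused candidate, and
#' the search stops after `max_stale` consecutive expansions without an
#' improvement of the best score (or when the open list is exhausted).
#' Score ties prefer the smaller subset, then the lexicographically earlier
#' feature set, so the search is fully deterministic.
#'
#' @inheritParams loo_bacc
#' @param candidates Character vector of candidate feature ids, typically
#'   the output of [mcone()].
#' @param max_stale Positive number of consecutive non-improving expansions
#'   tolerated before termination; `Inf` explores the whole power set.
#'   Default 5.
#' @return An object of class `best_first_fit`: list with `selected`
#'   (feature ids), `objective` (the subset's LOO balanced accuracy),
#'   `trail` (tibble of every subset scored, in visit order) and
#'   `n_evaluations`.
#' @export
best_first <- function(data, label, candidates, max_stale = 5,
                       positive = NULL) {
  check_max_stale(max_stale)
  d <- as_fs(data, {{ label }}, positive = positive)
  candidates <- check_subset(d, candidates, arg = "candidates")
  res <- best_first_impl(d$x, d$y, candidates, max_stale)
  structure(c(res, list(max_stale = max_stale)), class = "best_first_fit")
}

check_max_stale <- function(max_stale) {
  if (!is.numeric(max_stale) || length(max_stale) != 1 || is.na(max_stale) ||
      max_stale < 1) {
    abort("`max_stale` must be a positive number (Inf for full exploration).")
  }
}

#' @export
print.best_first_fit <- function(x, ...) {
  cat(sprintf("best-first search: %d subsets scored, objective LOO BAcc = %.4f\n",
              x$n_evaluations, x$objective))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' McTwo: two-step feature selection
#'
#' Runs the full two-step selector: the [mcone()] MIC filter, then a
#' [best_first()] wrapper search over the filter's output, scored by the
#' leave-one-out balanced accuracy of a 1-nearest-neighbour classifier. The
#' final subset is therefore at most as large as the filter's, usually far
#' smaller.
#'
#' @inheritParams mcone
#' @inheritParams best_first
#' @return An object of class `mctwo_fit`: list with `selected` (final
#'   feature ids), `objective` (their LOO balanced accuracy), `mcone`
#'   (the stage-one [mcone()] fit), `trail` (wrapper search trail),
#'   `counters` (MIC and subset-evaluation counts) and `params`. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' d <- synth_data(n_pos = 20, n_neg = 20, n_noise = 30, seed = 1)
#' fit <- mctwo(d, label)
#' fit
#' @export
mctwo <- function(data, label, r = 0.2, max_stale = 5, positive = NULL,
                  alpha = 0.6, clumps = 15) {
  check_r(r)
  check_max_stale(max_stale)
  d <- as_fs(data, {{ label }}, positive = positive)
  stage1 <- mcone_impl(d, r, alpha, clumps)
  if (length(stage1$selected) == 0) {
    abort(c("the MIC relevance filter selected no features.",
            i = sprintf("no feature has MIC(F, C) > r = %g on these %d features; try a lower `r`.",
                        r, length(d$feature_ids))),
          class = "mctwo_empty_selection")
  }
  fit1 <- new_mcone_fit(stage1, d, r, alpha, clumps)
  stage2 <- best_first_impl(d$x, d$y, stage1$selected, max_stale)
  structure(
    list(selected = stage2$selected,
         objective = stage2$objective,
         mcone = fit1,
         trail = stage2$trail,
         counters = list(label_mic = stage1$n_label_mic,
                         pairwise_mic = stage1$n_pairwise_mic,
                         subset_evaluations = stage2$n_evaluations),
         params = list(r = r, max_stale = max_stale,
                       alpha = alpha, clumps = clumps),
         label = d$label_name,
         tokens = d$tokens),
    class = "mctwo_fit")
}

#' @export
print.mctwo_fit <- function(x, ...) {
  cat(sprintf("McTwo: %d features screened -> %d relevant -> %d after filter -> %d selected\n",
              nrow(x$mcone$relevance), sum(x$mcone$relevance$relevant),
              length(x$mcone$selected), length(x$selected)))
  cat(sprintf("objective (LOO BAcc of 1-NN): %.4f\n", x$objective))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
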