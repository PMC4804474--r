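#' Information-relevant features
#'
#' Returns the features whose MIC with the class label strictly exceeds the
#' irrelevancy threshold `r`, sorted by decreasing relevance (ties keep the
#' original feature order). This is the relevance screen of [mcone()]
#' exposed on its own.
#'
#' @inheritParams mic_relevance
#' @param r Irrelevancy threshold in \[0, 1): a feature is kept iff
#'   `MIC(feature, label) > r` (strict). Default 0.2.
#' @return A tibble with columns `feature` and `mic`, decreasing in `mic`.
#' @export
relevant_features <- function(data, label, r = 0.2, positive = NULL,
                              alpha = 0.6, clumps = 15) {
  check_r(r)
  rel <- mic_relevance(data, {{ label }}, positive = positive,
                       alpha = alpha, clumps = clumps)
  keep <- which(rel$mic > r)
  rel[keep[order(-rel$mic[keep])], ]
}

check_r <- function(r) {
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0 || r >= 1) {
    abort("`r` must be a single number in [0, 1) (with r = 1 no feature could pass).")
  }
}

# Core filter: relevance screen + greedy redundancy elimination under the
# information dominant criterion. Candidates are visited in decreasing
# MIC(F, C) order; a candidate F_i is discarded iff some already-kept F_j has
#   MIC(F_j, C) >= MIC(F_i, C)  and  MIC(F_j, F_i) >= MIC(F_i, C).
# Every kept feature satisfies the first clause by construction (greedy
# order; relevance ties resolve in favour of the feature kept first). Both
# comparisons are non-strict: under strict comparisons an exact duplicate
# of a kept feature would survive whenever the relevances tie — and always
# when a feature separates the classes perfectly (relevance 1 = pairwise
# MIC of the duplicate pair). Non-strict dominance mirrors the fast
# correlation-based filter scheme and differs from strict only on exact
# ties. Pairwise MICs are computed lazily, only kept-vs-candidate, so the
# call count is at most |relevant| * |selected|.
mcone_impl <- function(d, r, alpha, clumps) {
  k <- length(d$feature_ids)
  rel <- vapply(seq_len(k), function(j) {
    mic_screen(d$x[, j], d$y01, alpha, clumps)
  }, numeric(1))
  relevant <- which(rel > r)
  ord <- relevant[order(-rel[relevant])]  # stable: ties keep original order
  kept <- integer(0)
  n_pair <- 0L
  for (i in ord) {
    redundant <- FALSE
    for (j in kept) {  # rel[j] >= rel[i] for every kept j
      n_pair <- n_pair + 1L
      if (mic_screen(d$x[, i], d$x[, j], alpha, clumps) >= rel[i]) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  list(selected = d$feature_ids[kept],
       relevance = rel,
       relevant = d$feature_ids[relevant],
       n_label_mic = k,
       n_pairwise_mic = n_pair)
}

#' McOne: MIC relevance filtering with redundancy elimination
#'
#' The filter stage of the two-step selector. Features are first screened
#' for relevance (`MIC(F, C) > r`, strict); the surviving features are then
#' visited in decreasing relevance order and a candidate is discarded iff an
#' already-kept feature — at least as label-relevant, with exact relevance
#' ties resolved in favour of the feature kept first — is at least as
#' strongly associated with the candidate as the candidate is with the
#' label (the information dominant criterion). Dominance comparisons are
#' non-strict, so an exact duplicate of a kept feature is always
#' eliminated, even when the pair separates the classes perfectly; strict
#' and non-strict dominance differ only on such exact ties.
#' Inter-feature MIC values are
#' computed lazily, only for kept-vs-candidate pairs, so the pairwise cost
#' stays far below quadratic whenever the relevance screen removes most
#' features.
#'
#' Zero-variance features score 0 and never pass the (strict) threshold.
#' Relevance ties are broken by original feature order.
#'
#' @inheritParams relevant_features
#' @return An object of class `mcone_fit`: a list with elements
#'   `selected` (feature ids, decreasing relevance), `relevance` (tibble of
#'   all screened features with their MIC and status), `r`, `params`, and
#'   `counters` (`label_mic`, `pairwise_mic` evaluation counts). Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @examples
#' d <- synth_data(n_pos = 20, n_neg = 20, n_noise = 20, seed = 1)
#' fit <- mcone(d, label)
#' fit$selected
#' @export
mcone <- function(data, label, r = 0.2, positive = NULL,
                  alpha = 0.6, clumps = 15) {
  check_r(r)
  d <- as_fs(data, {{ label }}, positive = positive)
  res <- mcone_impl(d, r, alpha, clumps)
  new_mcone_fit(res, d, r, alpha, clumps)
}

new_mcone_fit <- function(res, d, r, alpha, clumps) {
  relevance <- tibble(
    feature = d$feature_ids,
    mic = res$relevance,
    relevant = d$feature_ids %in% res$relevant,
    selected = d$feature_ids %in% res$selected
  )
  structure(
    list(selected = res$selected,
         relevance = relevance,
         r = r,
         params = list(alpha = alpha, clumps = clumps),
         counters = list(label_mic = res$n_label_mic,
                         pairwise_mic = res$n_pairwise_mic),
         label = d$label_name,
         tokens = d$tokens),
    class = "mcone_fit")
}

#' @export
print.mcone_fit <- function(x, ...) {
  cat(sprintf("McOne filter (r = %g): %d/%d features relevant, %d selected\n",
              x$r, sum(x$relevance$relevant), nrow(x$relevance),
              length(x$selected)))
  cat(sprintf("MIC evaluations: %d feature-label, %d pairwise\n",
              x$counters$label_mic, x$counters$pairwise_mic))
  if (length(x$selected)) {
    cat("selected:", paste(head(x$selected, 10), collapse = ", "),
        if (length(x$selected) > 10) "..." else "", "\n")
  }
  invisible(x)
}
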