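# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (full enumeration, literal definitions)
# rather than sharing code paths with the implementation they check.

# Exhaustive MIC by full enumeration of axis cuts on BOTH axes; feasible for
# tiny n only (grids are limited to l * q <= max(n^0.6, 4)).
brute_mic_r <- function(x, y, alpha = 0.6) {
  n <- length(x)
  B <- max(n^alpha, 4)
  ordx <- order(x)
  ordy <- order(y)
  bx <- which(diff(x[ordx]) != 0)
  by <- which(diff(y[ordy]) != 0)
  assign_bins <- function(ord, cuts) {
    b <- integer(length(ord))
    r <- 1
    ci <- 1
    for (i in seq_along(ord)) {
      b[ord[i]] <- r
      if (ci <= length(cuts) && i == cuts[ci]) {
        r <- r + 1
        ci <- ci + 1
      }
    }
    b
  }
  best <- 0
  for (l in 2:floor(B / 2)) {
    for (q in 2:floor(B / l)) {
      if (length(bx) < l - 1 || length(by) < q - 1) next
      for (ccx in utils::combn(bx, l - 1, simplify = FALSE)) {
        px <- assign_bins(ordx, ccx)
        for (ccy in utils::combn(by, q - 1, simplify = FALSE)) {
          py <- assign_bins(ordy, ccy)
          p <- table(px, py) / n
          pr <- rowSums(p)
          pc <- colSums(p)
          mi <- sum(ifelse(p > 0, p * log(p / outer(pr, pc)), 0))
          best <- max(best, mi / log(min(l, q)))
        }
      }
    }
  }
  best
}

# Literal application of the filter definitions: compute the full relevance
# vector and pairwise MIC matrix up front, then repeatedly keep the
# maximum-relevance candidate and drop every candidate redundant with an
# already-kept feature (a kept F_j — which has MIC(F_j, C) >= MIC(F_i, C)
# by construction, ties resolved by keep order — with
# MIC(F_j, F_i) >= MIC(F_i, C), non-strict dominance).
oracle_mcone <- function(data, r, alpha = 0.6, clumps = 15) {
  rel_tbl <- mic_relevance(data, label, alpha = alpha, clumps = clumps)
  rel <- stats::setNames(rel_tbl$mic, rel_tbl$feature)
  S <- rel_tbl$feature[rel_tbl$mic > r]
  if (length(S) == 0) return(character(0))
  M <- mic_matrix(data, features = S, alpha = alpha, clumps = clumps)
  kept <- character(0)
  cand <- S  # original feature order
  while (length(cand) > 0) {
    j <- cand[order(-rel[cand])][1]  # max relevance, ties original order
    kept <- c(kept, j)
    cand <- setdiff(cand, j)
    if (length(cand) > 0) {
      red <- vapply(cand, function(i) {
        any(M[kept, i] >= rel[i])  # kept features are >= relevant already
      }, logical(1))
      cand <- cand[!red]
    }
  }
  kept
}

# Exhaustive wrapper oracle: the maximum LOO balanced accuracy over every
# non-empty subset of the candidates.
oracle_best_subset <- function(data, cands) {
  best <- -Inf
  for (m in seq_along(cands)) {
    for (sub in utils::combn(cands, m, simplify = FALSE)) {
      best <- max(best, loo_bacc(data, label, sub))
    }
  }
  best
}

# Six-sample two-feature fixture whose LOO 1-NN confusion tally is derived
# by hand in test-wrapper.R (includes an exact three-way distance tie).
nn_fixture <- function() {
  tibble::tibble(
    sample = paste0("s", 1:6),
    label = c("N", "N", "N", "P", "P", "P"),
    f1 = c(0, 0, 1, 5, 5, 0.5),
    f2 = c(0, 1, 0, 5, 6, 0.5)
  )
}
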