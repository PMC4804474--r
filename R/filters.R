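# Baseline per-feature filter rankers: Welch t (TRank), Wilcoxon rank-sum
# with normal approximation and tie correction (WRank), and ROC AUC ranked
# by departure from 0.5 (ROCRank). All return a `feature_ranking` tibble
# sorted most- to least-discriminative; rank ties keep original feature
# order (stable).

rank_trank <- function(x, y) {
  p_idx <- y == "P"
  n1 <- sum(p_idx)
  n2 <- sum(!p_idx)
  m1 <- colMeans(x[p_idx, , drop = FALSE])
  m2 <- colMeans(x[!p_idx, , drop = FALSE])
  v1 <- apply(x[p_idx, , drop = FALSE], 2, var)
  v2 <- apply(x[!p_idx, , drop = FALSE], 2, var)
  se2 <- v1 / n1 + v2 / n2
  stat <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2),
                 ifelse(m1 == m2, 0, sign(m1 - m2) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               1)
  p <- ifelse(is.finite(stat), 2 * pt(-abs(stat), df), 0)
  p[stat == 0 & se2 == 0] <- 1  # identical degenerate groups: no evidence
  list(statistic = stat, p.value = p, score = p, decreasing = FALSE)
}

rank_wrank <- function(x, y) {
  p_idx <- y == "P"
  n1 <- sum(p_idx)
  n2 <- sum(!p_idx)
  n <- n1 + n2
  stat <- numeric(ncol(x))
  p <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j])
    u <- sum(r[p_idx]) - n1 * (n1 + 1) / 2  # Mann-Whitney U, ties at 1/2
    mu <- n1 * n2 / 2
    ties <- table(x[, j])
    sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0) {
      z <- if (u == mu) 0 else sign(u - mu) * Inf
    } else {
      z <- (u - mu) / sqrt(sig2)
    }
    stat[j] <- u
    p[j] <- if (is.finite(z)) 2 * pnorm(-abs(z)) else 0
    if (z == 0 && sig2 <= 0) p[j] <- 1  # all values tied: no information
  }
  list(statistic = stat, p.value = p, score = p, decreasing = FALSE)
}

rank_rocrank <- function(x, y) {
  p_idx <- y == "P"
  n1 <- sum(p_idx)
  n2 <- sum(!p_idx)
  auc <- vapply(seq_len(ncol(x)), function(j) {
    r <- rank(x[, j])
    (sum(r[p_idx]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  }, numeric(1))
  list(statistic = auc, p.value = rep(NA_real_, ncol(x)),
       score = abs(auc - 0.5), decreasing = TRUE)
}

#' Baseline filter rankers: TRank, WRank, ROCRank
#'
#' Orders features most- to least-discriminative by a per-feature
#' statistic:
#' \describe{
#'   \item{`trank`}{Welch (unequal-variance) two-sample t test; ranked by
#'     ascending p-value. Identical degenerate groups (zero pooled spread,
#'     zero difference) get `p = 1` and rank last.}
#'   \item{`wrank`}{Wilcoxon rank-sum via the Mann-Whitney U statistic with
#'     normal approximation and tie correction; ranked by ascending
#'     p-value. All-tied features get `p = 1`.}
#'   \item{`rocrank`}{Area under the ROC curve computed by the rank
#'     formulation (ties counted 1/2); ranked by `|AUC - 0.5|` descending,
#'     so both up- and down-regulated features rank early.}
#' }
#' Rank ties keep the original feature order.
#'
#' @inheritParams mic_relevance
#' @param method One of `"trank"`, `"wrank"`, `"rocrank"`.
#' @return A `feature_ranking` tibble with columns `feature`, `statistic`
#'   (t, U, or AUC), `p.value` (`NA` for rocrank), `score` (the ranking
#'   key) and `rank`, sorted by `rank`. Both classes need at least 2
#'   samples.
#' @examples
#' d <- synth_data(n_pos = 15, n_neg = 15, n_noise = 10, seed = 1)
#' rank_features(d, label, "trank")
#' @export
rank_features <- function(data, label, method = c("trank", "wrank", "rocrank"),
                          positive = NULL) {
  method <- match.arg(method)
  d <- as_fs(data, {{ label }}, positive = positive)
  if (min(table(d$y)) < 2) {
    abort("each class needs at least 2 samples for ranking statistics.")
  }
  res <- switch(method,
                trank = rank_trank(d$x, d$y),
                wrank = rank_wrank(d$x, d$y),
                rocrank = rank_rocrank(d$x, d$y))
  ord <- order(res$score, decreasing = res$decreasing)  # stable
  out <- tibble(feature = d$feature_ids[ord],
                statistic = unname(res$statistic[ord]),
                p.value = unname(res$p.value[ord]),
                score = unname(res$score[ord]),
                rank = seq_along(ord))
  structure(out, method = method,
            class = c("feature_ranking", class(out)))
}

#' First k features of a ranking
#'
#' Extracts the ids of the `k` most discriminative features. Used for the
#' fairness protocol when comparing filter rankers with a subset selector:
#' `k` is set to the size of the selector's subset.
#'
#' @param ranking A [rank_features()] result.
#' @param k Positive integer, at most the number of ranked features.
#' @return Character vector of `k` feature ids.
#' @export
top_k <- function(ranking, k) {
  if (!inherits(ranking, "feature_ranking")) {
    abort("`ranking` must be a feature_ranking (see rank_features()).")
  }
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1 ||
      k > nrow(ranking) || k != floor(k)) {
    abort(sprintf("`k` must be an integer in [1, %d].", nrow(ranking)))
  }
  ranking$feature[seq_len(k)]
}
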