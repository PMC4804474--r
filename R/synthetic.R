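# Synthetic benchmark generator: a Gaussian class-shift model producing the
# three feature roles the selector distinguishes — informative (class-shifted
# mean), redundant (noisy copy of an informative parent) and independent
# noise — in the "large p, small n" regime.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate a synthetic labelled expression dataset
#'
#' Draws a samples x features tibble with known ground truth:
#' \describe{
#'   \item{informative (`inf<j>`)}{`Normal(0, 1)` in the negative class,
#'     `Normal(delta, 1)` in the positive class — `delta` is the effect
#'     size in units of the within-class standard deviation.}
#'   \item{redundant (`red<j>_<c>`)}{copy `c` of informative parent
#'     `inf<j>` plus `Normal(0, rho)` copy noise; parents are assigned
#'     round-robin.}
#'   \item{noise (`noise<m>`)}{`Normal(0, 1)`, independent of the labels.}
#' }
#' Defaults (50 + 50 samples, 2 informative with `delta = 2`, 4 redundant
#' with `rho = 0.3`, 194 noise) give a 200-feature dataset whose planted
#' signal a working selector should recover. The generator is deterministic
#' per `seed` and leaves the global RNG state untouched.
#'
#' @param n_pos,n_neg Positive/negative sample counts (each `>= 1`).
#' @param n_informative Number of class-shifted features (0 for a null
#'   dataset with labels independent of every feature).
#' @param n_redundant Number of noisy copies (requires
#'   `n_informative >= 1` unless 0).
#' @param n_noise Number of independent noise features.
#' @param delta Class mean shift of informative features. Default 2.
#' @param rho Copy-noise standard deviation of redundant features.
#'   Default 0.3.
#' @param seed Integer RNG seed. Default 1.
#' @return A tibble with columns `sample`, `label` (tokens `"N"`, `"P"`;
#'   negatives first) and one numeric column per feature. The ground-truth
#'   role map is attached as attribute `"truth"` and retrievable with
#'   [synth_truth()].
#' @examples
#' d <- synth_data(n_pos = 10, n_neg = 10, n_noise = 5, seed = 1)
#' synth_truth(d)
#' @export
synth_data <- function(n_pos = 50, n_neg = 50, n_informative = 2,
                       n_redundant = 4, n_noise = 194, delta = 2,
                       rho = 0.3, seed = 1) {
  if (n_pos < 1 || n_neg < 1) {
    abort("both classes need at least one sample (`n_pos`, `n_neg` >= 1).")
  }
  if (n_informative < 0 || n_redundant < 0 || n_noise < 0) {
    abort("feature counts must be non-negative.")
  }
  if (n_redundant > 0 && n_informative < 1) {
    abort("redundant features need at least one informative parent.")
  }
  k <- n_informative + n_redundant + n_noise
  if (k < 1) abort("at least one feature is required.")
  s <- n_pos + n_neg
  y <- rep(c("N", "P"), c(n_neg, n_pos))
  with_seed(seed, {
    x <- matrix(0, nrow = s, ncol = k)
    names_v <- character(k)
    role <- character(k)
    parent <- rep(NA_character_, k)
    j <- 0L
    inf_cols <- integer(n_informative)
    for (i in seq_len(n_informative)) {
      j <- j + 1L
      x[, j] <- rnorm(s, mean = ifelse(y == "P", delta, 0), sd = 1)
      names_v[j] <- sprintf("inf%d", i)
      role[j] <- "informative"
      inf_cols[i] <- j
    }
    for (i in seq_len(n_redundant)) {
      j <- j + 1L
      p <- ((i - 1) %% n_informative) + 1
      x[, j] <- x[, inf_cols[p]] + rnorm(s, 0, rho)
      names_v[j] <- sprintf("red%d_%d", p, ceiling(i / n_informative))
      role[j] <- "redundant"
      parent[j] <- sprintf("inf%d", p)
    }
    for (i in seq_len(n_noise)) {
      j <- j + 1L
      x[, j] <- rnorm(s)
      names_v[j] <- sprintf("noise%d", i)
      role[j] <- "noise"
    }
    colnames(x) <- names_v
    out <- dplyr::bind_cols(
      tibble(sample = sprintf("S%03d", seq_len(s)), label = y),
      as_tibble(x)
    )
    attr(out, "truth") <- tibble(feature = names_v, role = role,
                                 parent = parent)
    out
  })
}

#' Ground-truth feature roles of a synthetic dataset
#'
#' @param data A tibble produced by [synth_data()].
#' @return A tibble with columns `feature`, `role` (`"informative"`,
#'   `"redundant"`, `"noise"`) and `parent` (the informative lineage of a
#'   redundant feature, else `NA`).
#' @export
synth_truth <- function(data) {
  tr <- attr(data, "truth")
  if (is.null(tr)) abort("`data` carries no ground-truth attribute (not from synth_data()?).")
  tr
}
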