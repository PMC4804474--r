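toy_frame <- function(p_vals, n_vals, feature = "f") {
  out <- tibble::tibble(label = rep(c("P", "N"), c(length(p_vals), length(n_vals))))
  out[[feature]] <- c(p_vals, n_vals)
  out
}

test_that("Welch t statistic matches the closed form on toy groups", {
  d <- toy_frame(c(5, 6, 7), c(1, 2, 3))
  rk <- rank_features(d, label, "trank")
  # means 6 and 2, both variances 1: t = 4 / sqrt(1/3 + 1/3)
  expect_equal(rk$statistic, 4 / sqrt(2 / 3))
  sym <- toy_frame(c(1, 2, 3), c(1, 2, 3))
  expect_equal(rank_features(sym, label, "trank")$statistic, 0)
})

test_that("degenerate identical groups rank last with p = 1", {
  d <- synth_data(n_pos = 10, n_neg = 10, n_informative = 1, n_redundant = 0,
                  n_noise = 3, delta = 2, seed = 1)
  d$flat <- rep(7, 20)
  rk <- rank_features(d, label, "trank")
  expect_identical(rk$feature[nrow(rk)], "flat")
  expect_equal(rk$p.value[rk$feature == "flat"], 1)
})

test_that("rank-sum statistic attains its extreme under perfect 3v3 separation", {
  d <- toy_frame(c(10, 11, 12), c(1, 2, 3))
  rk <- rank_features(d, label, "wrank")
  expect_equal(rk$statistic, 9)  # U = n1 * n2: every P above every N
  d2 <- toy_frame(c(1, 2, 3), c(10, 11, 12))
  expect_equal(rank_features(d2, label, "wrank")$statistic, 0)
})

test_that("all-tied feature carries no rank-sum information (p = 1)", {
  d <- toy_frame(rep(4, 4), rep(4, 4))
  rk <- rank_features(d, label, "wrank")
  expect_equal(rk$p.value, 1)
})

test_that("normal-approximation rank-sum p is close to the exact permutation p", {
  p_vals <- c(1.2, 3.4, 2.2, 5.0)
  n_vals <- c(0.8, 1.2, 0.5, 2.0)  # one cross-group tie at 1.2
  d <- toy_frame(p_vals, n_vals)
  rk <- rank_features(d, label, "wrank")
  x <- c(p_vals, n_vals)
  # exact null: all 70 assignments of 4 of the 8 values to "P"
  r <- rank(x)
  u_obs <- sum(r[1:4]) - 4 * 5 / 2
  mu <- 4 * 4 / 2
  us <- vapply(utils::combn(8, 4, simplify = FALSE), function(idx) {
    sum(r[idx]) - 4 * 5 / 2
  }, numeric(1))
  p_exact <- mean(abs(us - mu) >= abs(u_obs - mu))
  expect_equal(rk$statistic, u_obs)
  expect_lt(abs(rk$p.value - p_exact), 0.15)
})

test_that("AUC reaches 1 for perfect separation and counts concordant pairs on toys", {
  d <- toy_frame(c(10, 11, 12), c(1, 2, 3))
  expect_equal(rank_features(d, label, "rocrank")$statistic, 1)
  d2 <- toy_frame(c(1, 3, 5), c(2, 4, 0))
  # concordant (P > N) pairs by hand: 1 beats 0; 3 beats 2, 0; 5 beats all
  expect_equal(rank_features(d2, label, "rocrank")$statistic, 6 / 9)
})

test_that("label-independent features sit near AUC 0.5", {
  set.seed(2)
  d <- tibble::tibble(label = rep(c("N", "P"), each = 250), f = rnorm(500))
  expect_lt(abs(rank_features(d, label, "rocrank")$statistic - 0.5), 0.1)
})

test_that("AUC of a negated feature complements to 1 on tie-free data", {
  set.seed(3)
  d <- tibble::tibble(label = rep(c("N", "P"), each = 10), f = rnorm(20))
  d$g <- -d$f
  rk <- rank_features(d, label, "rocrank")
  expect_equal(sum(rk$statistic), 1)
})

test_that("rank-sum and AUC rankers agree on tie-free data; only TRank reacts to monotone warping", {
  d <- synth_data(n_pos = 15, n_neg = 15, n_informative = 2, n_redundant = 0,
                  n_noise = 8, delta = 1.5, seed = 4)
  w <- rank_features(d, label, "wrank")
  a <- rank_features(d, label, "rocrank")
  expect_identical(w$feature, a$feature)
  # strictly monotone transform: exp()
  d2 <- d
  feats <- setdiff(names(d), c("sample", "label"))
  d2[feats] <- lapply(d2[feats], exp)
  expect_identical(rank_features(d2, label, "wrank")$feature, w$feature)
  expect_identical(rank_features(d2, label, "rocrank")$feature, a$feature)
  t1 <- rank_features(d, label, "trank")
  t2 <- rank_features(d2, label, "trank")
  expect_false(isTRUE(all.equal(
    t1$statistic[match(feats, t1$feature)],
    t2$statistic[match(feats, t2$feature)])))
})

test_that("top_k slices the head of a ranking and validates k", {
  d <- synth_data(n_pos = 10, n_neg = 10, n_informative = 1, n_redundant = 0,
                  n_noise = 4, delta = 3, seed = 5)
  rk <- rank_features(d, label, "trank")
  expect_identical(top_k(rk, nrow(rk)), rk$feature)
  expect_identical(top_k(rk, 1), "inf1")
  expect_error(top_k(rk, 0), "k")
  expect_error(top_k(rk, nrow(rk) + 1), "k")
  # fairness protocol: filter subset sized to the wrapper's selection
  fit <- mctwo(d, label)
  expect_length(top_k(rk, length(fit$selected)), length(fit$selected))
})

test_that("both classes need two samples for ranking statistics", {
  d <- tibble::tibble(label = c("P", "N", "N", "N"), f = 1:4)
  expect_error(rank_features(d, label, "trank"), "at least 2")
})
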