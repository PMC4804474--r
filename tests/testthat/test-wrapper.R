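test_that("LOO balanced accuracy is 1 for a perfectly separating feature", {
  d <- tibble::tibble(label = rep(c("N", "P"), each = 5),
                      f = rep(c(0, 1), each = 5))
  expect_equal(loo_bacc(d, label, "f"), 1)
})

test_that("a constant feature yields the degenerate all-negative predictor at BAcc 0.5", {
  # every query is equidistant from all others, so each is predicted "N":
  # Sn = 0, Sp = 1, BAcc = 1/2 regardless of class imbalance
  d <- tibble::tibble(label = rep(c("N", "P"), c(8, 2)), f = rep(1, 10))
  expect_equal(loo_bacc(d, label, "f"), 0.5)
})

test_that("LOO tally on the six-sample fixture matches the hand enumeration", {
  # nearest neighbours worked out by hand: s1,s2,s3 (all N) are closest to
  # the P sample s6 -> three FP; s4,s5 pair up -> two TP; s6 is equidistant
  # (d = sqrt(0.5)) from s1, s2 and s3, the tie goes to the smallest index
  # s1 -> FN. Sn = 2/3, Sp = 0, BAcc = 1/3.
  expect_equal(loo_bacc(nn_fixture(), label, c("f1", "f2")), 1 / 3)
})

test_that("loo_bacc validates its feature subset", {
  d <- nn_fixture()
  expect_error(loo_bacc(d, label, character(0)), "non-empty")
  expect_error(loo_bacc(d, label, "nope"), "unknown feature")
  expect_error(loo_bacc(d, label, c("f1", "f1")), "duplicates")
})

test_that("single-candidate search returns that candidate and its score", {
  d <- nn_fixture()
  fit <- best_first(d, label, "f1")
  expect_identical(fit$selected, "f1")
  expect_equal(fit$objective, loo_bacc(d, label, "f1"))
  expect_identical(fit$n_evaluations, 1L)
})

test_that("full exploration matches the exhaustive subset oracle", {
  for (i in 1:10) {
    d <- synth_data(n_pos = 8, n_neg = 8, n_informative = 2, n_redundant = 1,
                    n_noise = 3, delta = 1.5, seed = 200 + i)
    cands <- setdiff(names(d), c("sample", "label"))
    fit <- best_first(d, label, cands, max_stale = Inf)
    expect_equal(fit$objective, oracle_best_subset(d, cands))
    expect_equal(fit$n_evaluations, 2^length(cands) - 1)
    # returned subset really attains the reported objective
    expect_equal(loo_bacc(d, label, fit$selected), fit$objective)
    # the objective tops every subset on the trail
    expect_gte(fit$objective, max(fit$trail$bacc))
  }
})

test_that("planted informative features are recovered among noise candidates", {
  d <- synth_data(n_pos = 20, n_neg = 20, n_informative = 2, n_redundant = 0,
                  n_noise = 6, delta = 3, seed = 17)
  cands <- setdiff(names(d), c("sample", "label"))
  fit <- best_first(d, label, cands, max_stale = Inf)
  expect_true(all(c("inf1", "inf2") %in% fit$selected))
})

test_that("mctwo composes the two stages and never enlarges the filter output", {
  for (seed in c(21, 22, 23)) {
    d <- synth_data(n_pos = 20, n_neg = 20, n_informative = 2,
                    n_redundant = 2, n_noise = 20, seed = seed)
    fit <- mctwo(d, label)
    expect_lte(length(fit$selected), length(fit$mcone$selected))
    expect_true(all(fit$selected %in% fit$mcone$selected))
    expect_equal(loo_bacc(d, label, fit$selected), fit$objective)
  }
})

test_that("a single-feature filter output passes through unchanged", {
  d <- synth_data(n_pos = 12, n_neg = 12, n_informative = 0, n_redundant = 0,
                  n_noise = 5, seed = 24)
  d$oracle <- as.numeric(d$label == "P")
  fit <- mctwo(d, label, r = 0.95)  # only the planted oracle feature passes
  expect_identical(fit$mcone$selected, "oracle")
  expect_identical(fit$selected, "oracle")
  expect_equal(fit$objective, 1)
})

test_that("an empty filter stage raises a structured error advising a lower r", {
  d <- synth_data(n_pos = 15, n_neg = 15, n_informative = 0, n_redundant = 0,
                  n_noise = 8, seed = 25)
  expect_error(mctwo(d, label, r = 0.95), class = "mctwo_empty_selection")
  expect_error(mctwo(d, label, r = 0.95), "lower `r`")
})

test_that("the selector is deterministic: identical inputs give identical fits", {
  d <- synth_data(n_pos = 20, n_neg = 20, n_informative = 2, n_redundant = 2,
                  n_noise = 30, seed = 26)
  f1 <- mctwo(d, label)
  f2 <- mctwo(d, label)
  expect_identical(f1$selected, f2$selected)
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$trail, f2$trail)
})

test_that("search cost counters stay within the quadratic envelope", {
  sizes <- c(20, 40, 80)
  for (p in sizes) {
    d <- synth_data(n_pos = 15, n_neg = 15, n_informative = 2,
                    n_redundant = 0, n_noise = p - 2, seed = 30 + p)
    fit <- mctwo(d, label)
    total_mic <- fit$counters$label_mic + fit$counters$pairwise_mic
    expect_lte(total_mic, p + p * (p - 1) / 2)
  }
})
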