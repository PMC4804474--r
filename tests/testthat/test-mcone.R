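test_that("a feature identical to the label vector is always selected", {
  set.seed(1)
  d <- synth_data(n_pos = 15, n_neg = 15, n_informative = 0, n_redundant = 0,
                  n_noise = 4, seed = 1)
  d$oracle <- as.numeric(d$label == "P")
  for (r in c(0, 0.5, 0.99)) {
    fit <- mcone(d, label, r = r)
    expect_true("oracle" %in% fit$selected)
  }
})

test_that("relevance threshold is strict: zero-variance features never pass at r = 0", {
  d <- synth_data(n_pos = 10, n_neg = 10, n_noise = 3, n_informative = 1,
                  n_redundant = 0, delta = 3, seed = 2)
  d$flat <- 1
  fit <- mcone(d, label, r = 0)
  expect_false("flat" %in% fit$selected)
  expect_identical(fit$relevance$mic[fit$relevance$feature == "flat"], 0)
  rel <- relevant_features(d, label, r = 0)
  expect_false("flat" %in% rel$feature)
})

test_that("an exact duplicate of an informative feature is eliminated as redundant", {
  d <- synth_data(n_pos = 20, n_neg = 20, n_informative = 1, n_redundant = 0,
                  n_noise = 3, delta = 3, seed = 3)
  d$dup <- d$inf1  # MIC(inf1, dup) = 1 dominates anything
  fit <- mcone(d, label, r = 0.1)
  expect_equal(sum(c("inf1", "dup") %in% fit$selected), 1)
})

test_that("greedy filter matches the literal definition oracle on randomised datasets", {
  for (i in 1:30) {
    d <- synth_data(n_pos = sample(8:20, 1), n_neg = sample(8:20, 1),
                    n_informative = sample(0:2, 1), n_redundant = 0,
                    n_noise = sample(3:8, 1), delta = 2.5, seed = 1000 + i)
    r <- sample(c(0, 0.1, 0.2, 0.3), 1)
    fit <- mcone(d, label, r = r)
    expect_identical(fit$selected, oracle_mcone(d, r))
  }
})

test_that("selection is invariant under feature-column permutation for distinct relevances", {
  d <- synth_data(n_pos = 20, n_neg = 20, n_informative = 2, n_redundant = 2,
                  n_noise = 6, delta = 2.5, seed = 4)
  fit <- mcone(d, label, r = 0.1)
  expect_gt(length(fit$selected), 0)
  rel <- fit$relevance$mic[fit$relevance$relevant]
  skip_if(anyDuplicated(rel) > 0, "tied relevance values in this draw")
  set.seed(9)
  feats <- setdiff(names(d), c("sample", "label"))
  d2 <- d[c("sample", "label", sample(feats))]
  fit2 <- mcone(d2, label, r = 0.1)
  expect_setequal(fit$selected, fit2$selected)
})

test_that("adding pure-noise features never evicts a selected feature", {
  # conditions where the planted signal clears the finite-sample MIC null:
  # a noise column could only evict a selected feature by out-scoring it
  for (seed in 1:5) {
    d <- synth_data(n_pos = 25, n_neg = 25, n_informative = 2,
                    n_redundant = 1, n_noise = 5, delta = 3, seed = seed)
    fit <- mcone(d, label, r = 0.3)
    expect_gt(length(fit$selected), 0)
    set.seed(100 + seed)
    extra <- matrix(rnorm(50 * 10), 50,
                    dimnames = list(NULL, paste0("extra", 1:10)))
    d2 <- dplyr::bind_cols(d, tibble::as_tibble(extra))
    fit2 <- mcone(d2, label, r = 0.3)
    expect_true(all(fit$selected %in% fit2$selected))
  }
})

test_that("nothing relevant means empty selection and zero pairwise MIC work", {
  d <- synth_data(n_pos = 15, n_neg = 15, n_informative = 0, n_redundant = 0,
                  n_noise = 10, seed = 6)
  fit <- mcone(d, label, r = 0.95)
  expect_length(fit$selected, 0)
  expect_identical(fit$counters$pairwise_mic, 0L)
})

test_that("stage sizes nest and the lazy pairwise counter is bounded", {
  d <- synth_data(n_pos = 25, n_neg = 25, n_informative = 2, n_redundant = 3,
                  n_noise = 30, seed = 7)
  fit <- mcone(d, label, r = 0.2)
  g <- glance(fit)
  expect_lte(g$n_selected, g$n_relevant)
  expect_lte(g$n_relevant, g$n_features)
  expect_lte(g$pairwise_mic, g$n_relevant * g$n_selected)
  expect_identical(g$label_mic, g$n_features)
  # selection order is descending relevance
  rel <- fit$relevance$mic[match(fit$selected, fit$relevance$feature)]
  expect_true(all(diff(rel) <= 0))
})

test_that("threshold validation rejects r outside [0, 1)", {
  d <- synth_data(n_pos = 5, n_neg = 5, n_noise = 2, seed = 8)
  expect_error(mcone(d, label, r = 1), "r")
  expect_error(mcone(d, label, r = -0.1), "r")
})
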