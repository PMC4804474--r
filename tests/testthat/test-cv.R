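test_that("internal CV produces one record per run x fold x classifier", {
  d <- synth_data(n_pos = 15, n_neg = 15, n_informative = 1, n_redundant = 0,
                  n_noise = 10, delta = 3, seed = 1)
  cv <- internal_cv(d, label, selector_rank("trank", 1),
                    classifiers = c("NN", "DTree"), runs = 3, folds = 5,
                    seed = 2)
  expect_equal(nrow(cv$records), 3 * 5 * 2)
  expect_identical(sort(unique(cv$records$classifier)), c("DTree", "NN"))
  expect_length(cv$seeds, 3)
  expect_true(all(cv$records$acc >= 0 & cv$records$acc <= 1))
  expect_true(all(cv$records$avc >= 0 & cv$records$avc <= 1))
})

test_that("a separable dataset is classified perfectly with the identity selector", {
  d <- synth_data(n_pos = 15, n_neg = 15, n_informative = 2, n_redundant = 0,
                  n_noise = 0, delta = 8, seed = 3)
  cv <- internal_cv(d, label, selector_all(), "NN", runs = 2, folds = 5,
                    seed = 4)
  expect_equal(cv$summary$mean_acc, 1)
  expect_equal(unique(cv$records$n_features), 2)
})

test_that("identical seed lists reproduce a bit-identical report", {
  d <- synth_data(n_pos = 12, n_neg = 12, n_informative = 1, n_redundant = 0,
                  n_noise = 8, seed = 5)
  cv1 <- internal_cv(d, label, selector_rank("wrank", 2), "NN", runs = 2,
                     folds = 4, seed = 6)
  cv2 <- internal_cv(d, label, selector_rank("wrank", 2), "NN", runs = 2,
                     folds = 4, seed = 6)
  expect_identical(cv1$records, cv2$records)
  expect_identical(cv1$summary, cv2$summary)
})

test_that("internal CV with the identity selector equals plain cross-validated classification", {
  d <- synth_data(n_pos = 10, n_neg = 10, n_informative = 1, n_redundant = 0,
                  n_noise = 3, delta = 2, seed = 7)
  seed <- 11
  cv <- internal_cv(d, label, selector_all(), "NN", runs = 1, folds = 5,
                    seed = seed)
  # replay the harness by hand: same stratified folds, no selection step
  y <- factor(ifelse(d$label == "P", "P", "N"), levels = c("N", "P"))
  set.seed(seed)
  fold_of <- integer(nrow(d))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold_of[idx] <- sample(rep_len(1:5, length(idx)))
  }
  for (f in 1:5) {
    pred <- train_predict(d[fold_of != f, ], label,
                          d[fold_of == f, , drop = FALSE], method = "NN")
    acc <- mean(as.character(pred) == d$label[fold_of == f])
    expect_equal(cv$records$acc[cv$records$fold == f], acc)
  }
})

test_that("an empty selection falls back to the majority-class predictor", {
  d <- synth_data(n_pos = 20, n_neg = 30, n_informative = 0, n_redundant = 0,
                  n_noise = 5, seed = 8)
  none <- function(data, label) character(0)
  cv <- internal_cv(d, label, none, "NN", runs = 2, folds = 5, seed = 9)
  # every test sample is predicted "N" (the training majority), so pooled
  # accuracy per run is exactly the majority rate
  pooled <- dplyr::summarise(
    dplyr::group_by(cv$records, .data$run),
    acc = (sum(.data$tp) + sum(.data$tn)) / 50)
  expect_equal(pooled$acc, rep(30 / 50, 2))
  expect_equal(unique(cv$records$n_features), 0)
})

test_that("external CV compares selectors on identical folds", {
  d <- synth_data(n_pos = 15, n_neg = 15, n_informative = 1, n_redundant = 0,
                  n_noise = 10, delta = 3, seed = 10)
  cv <- external_cv(d, label,
                    selectors = list(TRank1 = selector_rank("trank", 1),
                                     WRank1 = selector_rank("wrank", 1)),
                    classifiers = "NN", runs = 2, folds = 5, seed = 12)
  expect_equal(nrow(cv$records), 2 * 2 * 5)
  expect_setequal(unique(cv$records$selector), c("TRank1", "WRank1"))
  # identical fold structure: per-fold test-set sizes agree across selectors
  sizes <- with(cv$records, tapply(tp + fn + tn + fp,
                                   list(selector, paste(run, fold)), unique))
  expect_equal(sizes["TRank1", ], sizes["WRank1", ])
  expect_s3_class(macc(cv), "tbl_df")
  expect_equal(nrow(macc(cv)), 2)
})

test_that("folds exceeding the smallest class are rejected", {
  d <- synth_data(n_pos = 3, n_neg = 20, n_noise = 3, n_informative = 0,
                  n_redundant = 0, seed = 13)
  expect_error(internal_cv(d, label, selector_all(), "NN", runs = 1,
                           folds = 5, seed = 1),
               "stratified")
})

test_that("cv reports support tidy, glance and paired comparison", {
  d <- synth_data(n_pos = 12, n_neg = 12, n_informative = 1, n_redundant = 0,
                  n_noise = 6, delta = 2.5, seed = 14)
  cv1 <- internal_cv(d, label, selector_rank("trank", 1), "NN", runs = 2,
                     folds = 4, seed = 15)
  cv2 <- internal_cv(d, label, selector_rank("trank", 3), "NN", runs = 2,
                     folds = 4, seed = 15)
  expect_identical(tidy(cv1), cv1$records)
  expect_identical(glance(cv1), cv1$summary)
  pc <- paired_comparison(cv1, cv2)
  expect_true(is.finite(pc$p.value) || pc$p.value %in% c(0, 1))
  expect_equal(pc$df, 2 * 4 - 1)
})
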