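# Downstream classifiers used to evaluate selected feature subsets.
# NN (1-nearest-neighbour) is implemented natively with the same distance
# and tie rules as the wrapper objective; SVM (linear kernel), Naive Bayes
# (Gaussian) and the CART-style decision tree are thin adapters over
# e1071 and rpart with default settings — evaluation instruments, not
# tunable models.

classifier_methods <- c("NN", "SVM", "NBayes", "DTree")

predict_nn <- function(xtr, ytr, xte) {
  if (nrow(xte) == 0) return(factor(character(0), levels = c("N", "P")))
  pred <- character(nrow(xte))
  for (i in seq_len(nrow(xte))) {
    di <- sqrt(colSums((t(xtr) - xte[i, ])^2))
    if (max(di) - min(di) <= 1e-12 * (1 + max(di))) {
      pred[i] <- "N"  # no usable signal: degenerate negative prediction
    } else {
      pred[i] <- as.character(ytr[which.min(di)])  # tie: smaller index
    }
  }
  factor(pred, levels = c("N", "P"))
}

predict_matrix <- function(method, xtr, ytr, xte) {
  if (nrow(xte) == 0) return(factor(character(0), levels = c("N", "P")))
  safe <- sprintf("V%d", seq_len(ncol(xtr)))
  switch(method,
    NN = predict_nn(xtr, ytr, xte),
    SVM = {
      fit <- e1071::svm(x = xtr, y = ytr, kernel = "linear", scale = FALSE)
      factor(as.character(predict(fit, xte)), levels = c("N", "P"))
    },
    NBayes = {
      dtr <- as.data.frame(xtr)
      names(dtr) <- safe
      dte <- as.data.frame(xte)
      names(dte) <- safe
      fit <- e1071::naiveBayes(x = dtr, y = ytr)
      factor(as.character(predict(fit, dte, eps = 1e-9)),
             levels = c("N", "P"))
    },
    DTree = {
      dtr <- as.data.frame(xtr)
      names(dtr) <- safe
      dtr$.y <- ytr
      dte <- as.data.frame(xte)
      names(dte) <- safe
      fit <- rpart::rpart(.y ~ ., data = dtr, method = "class")
      factor(as.character(predict(fit, dte, type = "class")),
             levels = c("N", "P"))
    },
    abort(sprintf("unknown classifier %s; available: %s.", dQuote(method),
                  paste(classifier_methods, collapse = ", ")))
  )
}

#' Train a classifier and predict test samples
#'
#' Fits one of the four evaluation classifiers on the training frame
#' (restricted to `features`, or all numeric columns) and predicts the
#' class of each test sample. `"NN"` is the native 1-nearest-neighbour
#' rule (Euclidean distance, distance ties to the smaller training index,
#' all-equidistant queries predicted `"N"`); `"SVM"` a linear-kernel
#' support vector machine, `"NBayes"` Gaussian naive Bayes, `"DTree"` a
#' CART decision tree, each with library defaults.
#'
#' @param train A data frame of training samples with a label column.
#' @param label Unquoted label column name in `train`.
#' @param test A data frame of test samples carrying the same feature
#'   columns (a label column, if present, is ignored).
#' @param method One of `"NN"`, `"SVM"`, `"NBayes"`, `"DTree"`.
#' @param features Optional character vector of feature columns to use.
#' @param positive Optional label token treated as the positive class.
#' @return Factor of predicted classes with levels `c("N", "P")`, one per
#'   test row (empty for an empty test frame).
#' @examples
#' d <- synth_data(n_pos = 15, n_neg = 15, n_noise = 3, seed = 1)
#' train_predict(d[1:20, ], label, d[21:30, ], method = "NN")
#' @export
train_predict <- function(train, label, test,
                          method = c("NN", "SVM", "NBayes", "DTree"),
                          features = NULL, positive = NULL) {
  method <- match.arg(method)
  d <- as_fs(train, {{ label }}, positive = positive, features = features)
  if (!is.data.frame(test)) abort("`test` must be a data frame.")
  missing_f <- setdiff(d$feature_ids, names(test))
  if (length(missing_f)) {
    abort(sprintf("test frame lacks feature column(s): %s.",
                  paste(dQuote(head(missing_f, 5)), collapse = ", ")))
  }
  xte <- as.matrix(test[d$feature_ids])
  storage.mode(xte) <- "double"
  if (nrow(xte) > 0 && !all(is.finite(xte))) {
    abort("test feature values must be finite.")
  }
  predict_matrix(method, d$x, d$y, xte)
}
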