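# Internal representation of a labelled dataset.
#
# User-facing functions take a tidy frame (samples in rows, one label column,
# numeric feature columns, optional `sample` id column) and are converted
# here to a samples x features matrix plus a two-level factor with the
# conventional levels c("N", "P").

as_fs <- function(data, label, positive = NULL, features = NULL) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame (samples in rows).")
  }
  lab_name <- as_name(enquo(label))
  if (!lab_name %in% names(data)) {
    abort(sprintf("label column `%s` not found in `data`.", lab_name))
  }
  labels_raw <- as.character(data[[lab_name]])
  if (anyNA(labels_raw)) abort("labels contain missing values.")
  tokens <- sort(unique(labels_raw))
  if (length(tokens) < 2) {
    abort(c("labels contain a single class; two classes are required.",
            i = sprintf("found only class token %s.", dQuote(tokens))),
          class = "mctwo_single_class")
  }
  if (length(tokens) > 2) {
    abort(sprintf("labels must be binary; found %d class tokens.",
                  length(tokens)))
  }
  # first token in lexicographic order maps to N unless overridden
  if (!is.null(positive)) {
    if (!positive %in% tokens) {
      abort(sprintf("`positive` class %s not among label tokens %s.",
                    dQuote(positive), paste(dQuote(tokens), collapse = ", ")))
    }
    tok_p <- positive
    tok_n <- setdiff(tokens, positive)
  } else {
    tok_n <- tokens[1]
    tok_p <- tokens[2]
  }
  y <- factor(ifelse(labels_raw == tok_p, "P", "N"), levels = c("N", "P"))

  sample_ids <- if ("sample" %in% names(data) && !identical("sample", lab_name)) {
    as.character(data[["sample"]])
  } else {
    sprintf("S%d", seq_len(nrow(data)))
  }
  if (anyDuplicated(sample_ids)) abort("sample ids must be unique.")

  if (is.null(features)) {
    is_num <- vapply(data, is.numeric, logical(1))
    features <- setdiff(names(data)[is_num], lab_name)
  } else {
    missing_f <- setdiff(features, names(data))
    if (length(missing_f)) {
      abort(sprintf("unknown feature column(s): %s.",
                    paste(dQuote(missing_f), collapse = ", ")))
    }
  }
  if (length(features) < 1) abort("no numeric feature columns found.")
  if (anyDuplicated(features)) abort("feature ids must be unique.")
  x <- as.matrix(data[features])
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) {
    abort("feature values must be finite (no NA/NaN/Inf).")
  }
  if (nrow(x) < 2) abort("at least two samples are required.")
  rownames(x) <- sample_ids
  list(x = x, y = y, y01 = as.double(y == "P"),
       feature_ids = features, sample_ids = sample_ids,
       tokens = c(N = tok_n, P = tok_p), label_name = lab_name)
}

check_subset <- function(d, features, arg = "features") {
  features <- as.character(features)
  if (length(features) == 0) abort(sprintf("`%s` must be non-empty.", arg))
  unknown <- setdiff(features, d$feature_ids)
  if (length(unknown)) {
    abort(sprintf("unknown feature id(s) in `%s`: %s.", arg,
                  paste(dQuote(unknown), collapse = ", ")))
  }
  if (anyDuplicated(features)) abort(sprintf("`%s` contains duplicates.", arg))
  features
}
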