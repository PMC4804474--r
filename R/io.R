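# On-disk interchange: expression matrices as TSV/CSV in the microarray
# convention (features in rows, first column the feature id, header row the
# sample ids) and labels as a two-column headerless TSV (sample id, class
# token). Values are written with 17 significant digits so a write/read
# round trip reproduces doubles bit-identically.

delim_of <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix and labels into a tidy frame
#'
#' Reads a feature-by-sample expression matrix (TSV or CSV by file
#' extension; first column feature ids, header row sample ids) and a
#' two-column headerless labels TSV (sample id, class token), and
#' assembles the samples x features tibble the selectors consume. Labels
#' must cover exactly the matrix's samples; the lexicographically first
#' class token is treated as the negative class unless `positive` is
#' given.
#'
#' @param matrix_path Path to the expression matrix.
#' @param labels_path Path to the labels file.
#' @param positive Optional class token to treat as positive.
#' @param transpose Set `TRUE` if the matrix file is samples-in-rows
#'   (first column sample ids, header row feature ids).
#' @return A tibble with columns `sample`, `label` and one numeric column
#'   per feature.
#' @export
read_dataset <- function(matrix_path, labels_path, positive = NULL,
                         transpose = FALSE) {
  if (!file.exists(matrix_path)) {
    abort(sprintf("expression matrix file not found: %s.", matrix_path))
  }
  if (!file.exists(labels_path)) {
    abort(sprintf("labels file not found: %s.", labels_path))
  }
  # read numerics as text and convert with strtod: exact to the last bit,
  # which the stream parser's fast float path is not
  m <- readr::read_delim(matrix_path, delim = delim_of(matrix_path),
                         col_types = readr::cols(.default = "c"),
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(m) < 2) abort("expression matrix needs an id column and at least one data column.")
  ids <- as.character(m[[1]])
  vals <- vapply(m[-1], as.double, numeric(nrow(m)))
  if (nrow(m) == 1) vals <- matrix(vals, nrow = 1)
  if (transpose) {
    sample_ids <- ids
    feature_ids <- colnames(m)[-1]
    x <- vals
  } else {
    feature_ids <- ids
    sample_ids <- colnames(m)[-1]
    x <- t(vals)
  }
  if (anyDuplicated(feature_ids)) abort("duplicate feature ids in the expression matrix.")
  if (anyDuplicated(sample_ids)) abort("duplicate sample ids in the expression matrix.")
  if (!all(is.finite(x))) abort("expression matrix contains missing or non-finite values.")

  lab <- readr::read_tsv(labels_path, col_names = FALSE,
                         show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (ncol(lab) < 2) abort("labels file must have two columns: sample id, class token.")
  lab_ids <- as.character(lab[[1]])
  lab_tok <- as.character(lab[[2]])
  unknown <- setdiff(lab_ids, sample_ids)
  if (length(unknown)) {
    abort(sprintf("labels mention unknown sample id(s): %s.",
                  paste(dQuote(head(unknown, 5)), collapse = ", ")))
  }
  missing_l <- setdiff(sample_ids, lab_ids)
  if (length(missing_l)) {
    abort(sprintf("labels missing for sample(s): %s.",
                  paste(dQuote(head(missing_l, 5)), collapse = ", ")))
  }
  tok <- lab_tok[match(sample_ids, lab_ids)]
  out <- dplyr::bind_cols(tibble(sample = sample_ids, label = tok),
                          as_tibble(`colnames<-`(x, feature_ids)))
  # validate (two classes, finiteness) and honour `positive` early
  as_fs(out, "label", positive = positive)
  out
}

#' Write a tidy labelled dataset to matrix + labels files
#'
#' Inverse of [read_dataset()]: writes the feature-by-sample matrix
#' (features in rows, 17 significant digits — doubles round-trip
#' bit-identically) and the two-column labels TSV with the original class
#' tokens.
#'
#' @inheritParams mic_relevance
#' @param matrix_path,labels_path Output paths; the matrix delimiter
#'   follows the file extension (`.csv` comma, otherwise tab).
#' @return Invisibly, `data`.
#' @export
write_dataset <- function(data, label, matrix_path, labels_path) {
  d <- as_fs(data, {{ label }})
  sep <- delim_of(matrix_path)
  num <- apply(d$x, c(1, 2), function(v) sprintf("%.17g", v))
  lines <- c(
    paste(c("feature", d$sample_ids), collapse = sep),
    vapply(seq_along(d$feature_ids), function(j) {
      paste(c(d$feature_ids[j], num[, j]), collapse = sep)
    }, character(1))
  )
  writeLines(lines, matrix_path)
  raw_tokens <- unname(d$tokens[as.character(d$y)])
  writeLines(paste(d$sample_ids, raw_tokens, sep = "\t"), labels_path)
  invisible(data)
}
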