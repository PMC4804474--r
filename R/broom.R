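# broom-style accessors: tidy() returns the per-feature / per-record
# detail, glance() the one-row fit summary.

#' @method tidy mcone_fit
#' @export
tidy.mcone_fit <- function(x, ...) {
  x$relevance |>
    dplyr::arrange(dplyr::desc(.data$mic)) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' @method glance mcone_fit
#' @export
glance.mcone_fit <- function(x, ...) {
  tibble(n_features = nrow(x$relevance),
         n_relevant = sum(x$relevance$relevant),
         n_selected = length(x$selected),
         r = x$r,
         label_mic = x$counters$label_mic,
         pairwise_mic = x$counters$pairwise_mic)
}

#' @method tidy mctwo_fit
#' @export
tidy.mctwo_fit <- function(x, ...) {
  tidy(x$mcone) |>
    dplyr::mutate(in_final = .data$feature %in% x$selected)
}

#' @method glance mctwo_fit
#' @export
glance.mctwo_fit <- function(x, ...) {
  tibble(n_features = nrow(x$mcone$relevance),
         n_relevant = sum(x$mcone$relevance$relevant),
         n_filtered = length(x$mcone$selected),
         n_selected = length(x$selected),
         objective = x$objective,
         subset_evaluations = x$counters$subset_evaluations,
         pairwise_mic = x$counters$pairwise_mic,
         r = x$params$r,
         max_stale = x$params$max_stale)
}

#' @method tidy best_first_fit
#' @export
tidy.best_first_fit <- function(x, ...) x$trail

#' @method glance best_first_fit
#' @export
glance.best_first_fit <- function(x, ...) {
  tibble(n_selected = length(x$selected),
         objective = x$objective,
         subsets_scored = x$n_evaluations)
}

#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$records

#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) x$summary

#' @method tidy feature_ranking
#' @export
tidy.feature_ranking <- function(x, ...) {
  as_tibble(x)
}
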