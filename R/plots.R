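# ggplot2 autoplot methods for the fitted objects.

#' @method autoplot mcone_fit
#' @export
autoplot.mcone_fit <- function(object, ...) {
  dat <- tidy(object) |>
    dplyr::mutate(status = dplyr::case_when(
      .data$selected ~ "selected",
      .data$relevant ~ "relevant (redundant)",
      TRUE ~ "irrelevant"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank, y = .data$mic,
                                    colour = .data$status)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$r, linetype = "dashed") +
    ggplot2::labs(x = "relevance rank", y = "MIC(feature, label)",
                  colour = NULL,
                  title = sprintf("MIC relevance screen (r = %g)", object$r)) +
    ggplot2::theme_minimal()
}

#' @method autoplot mctwo_fit
#' @export
autoplot.mctwo_fit <- function(object, ...) {
  tr <- object$trail
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$bacc)) +
    ggplot2::geom_step(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$size), alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$objective, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::scale_size_continuous(breaks = unique(tr$size)) +
    ggplot2::labs(x = "subsets scored (visit order)",
                  y = "LOO balanced accuracy", size = "subset size",
                  title = "Best-first wrapper search trail") +
    ggplot2::theme_minimal()
}

#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, metric = "acc", ...) {
  rec <- object$records
  if ("selector" %in% names(rec)) {
    p <- ggplot2::ggplot(rec, ggplot2::aes(x = .data$selector,
                                           y = .data[[metric]],
                                           fill = .data$classifier))
  } else {
    p <- ggplot2::ggplot(rec, ggplot2::aes(x = .data$classifier,
                                           y = .data[[metric]]))
  }
  p + ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(y = sprintf("held-out %s (per fold)", metric), x = NULL,
                  title = sprintf("Cross-validation (%s)", object$scheme)) +
    ggplot2::theme_minimal()
}

#' @method autoplot feature_ranking
#' @export
autoplot.feature_ranking <- function(object, n = 20, ...) {
  dat <- head(as_tibble(object), n)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$feature,
                                                       -.data$rank),
                                    y = .data$score)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = sprintf("%s ranking score", attr(object, "method")),
                  title = sprintf("Top %d features (%s)", nrow(dat),
                                  attr(object, "method"))) +
    ggplot2::theme_minimal()
}
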