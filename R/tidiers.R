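#' Tidy and glance methods for calling results and evaluations
#'
#' `tidy()` returns the row-level content (variants, or the per-variant
#' evaluation audit); `glance()` a one-row summary.
#'
#' @param x A `rad_call` or `rad_eval` object.
#' @param ... Unused.
#' @return A tibble.
#' @name radbubbles-tidiers
NULL

#' @rdname radbubbles-tidiers
#' @export
tidy.rad_call <- function(x, ...) {
  select(x$variants, "bubble_id", "kind", "closure", "rank", "missing_frac",
         "cluster_id", "cluster_size", "path_a", "path_b")
}

#' @rdname radbubbles-tidiers
#' @export
glance.rad_call <- function(x, ...) x$stats

#' @rdname radbubbles-tidiers
#' @export
tidy.rad_eval <- function(x, ...) as_tibble(x$audit)

#' @rdname radbubbles-tidiers
#' @export
glance.rad_eval <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, recall = x$recall,
         precision = x$precision, n_predictions = x$n_predictions,
         n_truth = x$n_truth)
}

#' Plot methods
#'
#' `autoplot.rad_call()` shows the rank distribution of all detected variants
#' with the retention threshold; `autoplot.rad_eval()` the TP/FP/FN counts.
#'
#' @param object A `rad_call` or `rad_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name radbubbles-plots
NULL

#' @rdname radbubbles-plots
#' @export
autoplot.rad_call <- function(object, ...) {
  cov_ranks <- rank_variants(object$coverage)
  ggplot2::ggplot(cov_ranks, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$config$min_rank,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "rank (max pairwise Phi of allele counts)", y = "variants",
      title = "Variant rank distribution",
      subtitle = sprintf("dashed line: retention threshold %.2f",
                         object$config$min_rank)
    )
}

#' @rdname radbubbles-plots
#' @export
autoplot.rad_eval <- function(object, ...) {
  df <- tibble(class = factor(c("TP", "FP", "FN"), levels = c("TP", "FP", "FN")),
               count = c(object$tp, object$fp, object$fn))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$count)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(
      x = NULL, y = "variant sites",
      title = "Evaluation against simulation truth",
      subtitle = sprintf("recall %.3f, precision %.3f",
                         object$recall, object$precision)
    )
}

#' Cluster size distribution of a calling result
#'
#' @param result A `rad_call` object.
#' @return A ggplot object.
#' @export
plot_cluster_sizes <- function(result) {
  df <- distinct(select(result$variants, "cluster_id", "cluster_size"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster_size)) +
    ggplot2::geom_bar(fill = "grey40") +
    ggplot2::labs(x = "variants per locus cluster", y = "clusters",
                  title = "RAD locus cluster sizes")
}
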