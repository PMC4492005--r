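#' Plot success rate against alignment score
#'
#' Success rate per score bin for each segment (V scores per base, D and J
#' raw), restricted by default to bins with more than 100 records.
#'
#' @param object A `vdj_evaluation` from [evaluate_success()].
#' @param min_bin_n Minimum records per bin to display. Default 100.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vdj_evaluation <- function(object, min_bin_n = 100, ...) {
  df <- dplyr::filter(object$score_bins, .data$n > min_bin_n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$success_rate)) +
    ggplot2::geom_line(linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~segment, scales = "free_x") +
    ggplot2::labs(x = "alignment score (V: per base)",
                  y = "success rate") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Histogram of approximate-minus-exhaustive score differences
#'
#' @param diffs Tibble from [score_difference()].
#' @param binwidth Histogram bin width. Default 1.
#' @return A ggplot object.
#' @export
plot_score_difference <- function(diffs, binwidth = 1) {
  df <- dplyr::filter(diffs, !is.na(.data$diff))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diff)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::labs(x = "approximate score - overlap DP score",
                  y = "rearrangements") +
    ggplot2::theme_minimal()
}

#' Success rate as a function of mutation probability
#'
#' @param sweep Tibble with columns `mutation_probability`, `segment`,
#'   `rate` (e.g. assembled from [glance.vdj_evaluation()] over a sweep).
#' @return A ggplot object.
#' @export
plot_success_sweep <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$mutation_probability,
                                      y = .data$rate,
                                      colour = .data$segment,
                                      shape = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mutation probability", y = "success rate") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
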