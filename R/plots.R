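# ggplot2 views of the main result types.

#' Plot a detection curve
#'
#' Mean detection fraction per family as a function of library sampling
#' depth, with a ribbon of +/- one replicate standard deviation.
#'
#' @param object A [subsample_detection()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.detection_curve <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$depth,
                                   y = 100 * .data$mean_fraction,
                                   colour = .data$family,
                                   fill = .data$family)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = 100 * pmax(.data$mean_fraction - .data$sd_fraction, 0),
      ymax = 100 * pmin(.data$mean_fraction + .data$sd_fraction, 1)),
      alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "library sampling depth (%)",
                  y = "germline insertions detected (%)",
                  colour = "family", fill = "family") +
    ggplot2::theme_minimal()
}

#' Plot a permutation test result
#'
#' Histogram of permuted mean percentiles with the observed mean marked.
#'
#' @param object A [permutation_test()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tibble(mean_percentile = object$null_means)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_percentile)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed_mean,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "mean percentile of gene length (from TSS)",
                  y = "permutations",
                  subtitle = sprintf("observed = %.1f, p = %.4g",
                                     object$observed_mean, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot per-insertion detection weights of a rate estimate
#'
#' @param object An [estimate_insertion_rate()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rate_estimate <- function(object, ...) {
  df <- object$per_insertion
  ggplot2::ggplot(df, ggplot2::aes(x = .data$vaf, y = .data$p_bar)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "variant allele fraction",
                  y = "mean detection probability (grid-averaged)") +
    ggplot2::theme_minimal()
}
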