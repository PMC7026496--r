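#' Plot the library-wide percent-killing distribution
#'
#' @param profile A [percent_killing()] profile.
#' @param thresholds Reference lines (percent killing).
#' @return A ggplot.
#' @export
plot_killing_distribution <- function(profile, thresholds = c(50, 75)) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$mean_killing)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::geom_vline(xintercept = thresholds, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Mean percent killing", y = "Compounds") +
    ggplot2::theme_minimal()
}

#' Plot a target/pathway vulnerability ranking
#'
#' @param ranking A [rank_vulnerability()] result.
#' @param top_n Groups shown.
#' @return A ggplot.
#' @export
plot_vulnerability <- function(ranking, top_n = 15) {
  dat <- head(ranking, top_n) |>
    mutate(group = factor(.data$group, levels = rev(.data$group)),
           label = sprintf("%d/%d", .data$k_above, .data$n_drugs))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$fraction, y = .data$group)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), hjust = -0.1,
                       size = 3) +
    ggplot2::scale_x_continuous(limits = c(0, 1.1), labels = function(x)
      scales_percent(x)) +
    ggplot2::labs(
      x = sprintf("Fraction of drugs > %g%% killing",
                  attr(ranking, "threshold")),
      y = NULL
    ) +
    ggplot2::theme_minimal()
}

scales_percent <- function(x) paste0(round(100 * x), "%")

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Dose-response curve with the fitted 4PL
#'
#' @param object A [fit_dose_response()] fit.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dose_response_fit
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$dose, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Dose", y = "Percent killing") +
    ggplot2::theme_minimal()
  if (object$converged) {
    grid <- tibble(dose = 10^seq(log10(min(object$data$dose)),
                                 log10(max(object$data$dose)),
                                 length.out = 200))
    grid$response <- object$bottom + (object$top - object$bottom) /
      (1 + 10^(object$hill * (log10(object$ic50) - log10(grid$dose))))
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Similarity heatmap of pairwise shared-mutation percentages
#'
#' @param sim A [pairwise_similarity()] result.
#' @return A ggplot.
#' @export
plot_similarity <- function(sim) {
  tidy(sim) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_a, y = .data$sample_b,
                                 fill = .data$jaccard_pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$jaccard_pct, 1)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 name = "Jaccard %") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Volcano plot of differential ubiquitination
#'
#' @param diff A [differential_test()] result.
#' @return A ggplot.
#' @export
plot_volcano <- function(diff) {
  ggplot2::ggplot(diff, ggplot2::aes(x = .data$log2fc,
                                     y = -log10(.data$p),
                                     colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(increased = "firebrick",
                                            decreased = "steelblue",
                                            unchanged = "grey70")) +
    ggplot2::labs(x = "log2 fold change (treated - vehicle)",
                  y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Mean growth curves per treatment arm
#'
#' @param records Growth tibble.
#' @return A ggplot.
#' @export
plot_growth_curves <- function(records) {
  growth_summary(records) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$day, y = .data$mean_volume,
                                 colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_volume - .data$sd_volume / sqrt(.data$n),
      ymax = .data$mean_volume + .data$sd_volume / sqrt(.data$n)
    )) +
    ggplot2::labs(x = "Day", y = expression(Mean~tumor~volume~(mm^3))) +
    ggplot2::theme_minimal()
}
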