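#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Interval plot of population-level effects
#'
#' Posterior means and 95% credible intervals of the population-level
#' coefficients of a fitted expectancy model.
#'
#' @param object An `expectancy_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot expectancy_fit
#' @export
autoplot.expectancy_fit <- function(object, ...) {
  tb <- generics::tidy(object)
  tb <- tb[grepl("^b_", tb$term), ]
  tb$term <- sub("^b_", "", tb$term)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "standardized effect (posterior mean, 95% CrI)",
                  y = NULL)
}

#' Expectancy-profile plot for one song
#'
#' Chord-wise predictor profiles (information content, entropy, sensory
#' distances) for a single song.
#'
#' @param frames Per-chord tibble with `song_id`, `position` and predictor
#'   columns.
#' @param song Song id to plot (default: first).
#' @param cols Predictor columns to show.
#' @return A ggplot object.
#' @export
plot_expectancy_profile <- function(frames, song = NULL,
                                    cols = intersect(c("ic_bits",
                                                       "entropy_bits",
                                                       "spectral_distance",
                                                       "tonal_dissimilarity"),
                                                     names(frames))) {
  if (is.null(song)) song <- frames$song_id[1]
  df <- frames |>
    dplyr::filter(.data$song_id == song) |>
    dplyr::select(dplyr::all_of(c("position", cols))) |>
    tidyr::pivot_longer(-"position", names_to = "predictor")
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~predictor, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "chord position", y = NULL, title = song)
}

#' ELPD comparison plot
#'
#' Dot-and-interval plot of the model comparison table from
#' [compare_elpd()].
#'
#' @param comparison Tibble returned by [compare_elpd()].
#' @return A ggplot object.
#' @export
plot_elpd_comparison <- function(comparison) {
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$elpd,
                               y = stats::reorder(.data$model, .data$elpd))) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$elpd - .data$se,
                                          xmax = .data$elpd + .data$se)) +
    ggplot2::labs(x = "expected log pointwise predictive density",
                  y = NULL)
}
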