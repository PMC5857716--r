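# ggplot2 views of the two tracks.

#' Identity-decay scatter with calibrated decay lines
#'
#' Percent identity against divergence age: points for fossil-dated pairs
#' (horizontal bars where only an age window is known) and one straight
#' decay line per calibrated rate.
#'
#' @param identity An identity tibble with age columns.
#' @param rates Optional list of [calibrate_rate()] objects (or
#'   Ma-per-percent values) drawn as reference lines.
#' @return A ggplot object.
#' @export
plot_identity_decay <- function(identity, rates = NULL) {
  df <- tibble::as_tibble(identity)
  df <- df[!is.na(df$divergence_age_ma) | !is.na(df$age_min_ma), ,
           drop = FALSE]
  df$age_plot_ma <- ifelse(is.na(df$divergence_age_ma),
                           (df$age_min_ma + df$age_max_ma) / 2,
                           df$divergence_age_ma)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$age_plot_ma,
                                        y = .data$identity_pct,
                                        colour = .data$subunit)) +
    ggplot2::geom_point(size = 2)
  if (any(!is.na(df$age_min_ma))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$age_min_ma, xmax = .data$age_max_ma),
      height = 0.6, na.rm = TRUE
    )
  }
  if (!is.null(rates)) {
    if (!is.list(rates)) rates <- list(rates)
    for (r in rates) {
      r <- as_decay_rate(r)
      p <- p + ggplot2::geom_abline(intercept = 100,
                                    slope = -1 / r$ma_per_pct,
                                    linetype = "dashed", colour = "grey40")
    }
  }
  p + ggplot2::labs(x = "Divergence age (Ma)", y = "Sequence identity (%)",
                    colour = "Comparison") +
    ggplot2::theme_minimal()
}

#' Node-age posteriors as a dot-and-interval plot
#'
#' @param object A `clock_posterior`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clock_posterior <- function(object, ...) {
  s <- summarize_posterior(object)
  ages <- s[s$kind == "age", ]
  ages$node <- stats::reorder(ages$node, ages$mean)
  ggplot2::ggplot(ages, ggplot2::aes(x = .data$mean, y = .data$node)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "Node age (Ma)", y = NULL,
                  title = "Posterior node ages (mean and 95% CI)") +
    ggplot2::theme_minimal()
}

#' Posterior mean rate against node age
#'
#' @param x A `clock_posterior` or the tibble from [rates_vs_time()].
#' @return A ggplot object.
#' @export
plot_rates_vs_time <- function(x) {
  df <- if (inherits(x, "clock_posterior")) rates_vs_time(x) else
    tibble::as_tibble(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_age_ma,
                                   y = .data$mean_rate_per_ga)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Posterior mean node age (Ma)",
                  y = "Rate (changes/site/Ga)") +
    ggplot2::theme_minimal()
}

#' Paired node ages across calibration variants
#'
#' Baseline posterior mean ages on the x axis against each variant on the
#' y axis; points off the identity line show nodes whose ages move when
#' calibrations change.
#'
#' @param object A `calibration_sensitivity` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration_sensitivity <- function(object, ...) {
  df <- object$pairs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$baseline_mean_ma,
                                   y = .data$mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "red") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~variant) +
    ggplot2::labs(x = "Baseline posterior mean age (Ma)",
                  y = "Variant posterior mean age (Ma)") +
    ggplot2::theme_minimal()
}
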