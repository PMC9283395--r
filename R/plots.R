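# ggplot2 displays for fitted models, model checks, and seasonal series.

#' Coefficient interval plot
#'
#' Forest-style display of posterior means with 95% and 50% credible
#' intervals, separated by model level and ordered by effect size. Filled
#' black points mark coefficients whose 95% interval excludes zero, gray
#' those whose 50% interval excludes zero, open circles the rest.
#'
#' @param object an `fgcm_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fgcm_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$level %in% c("level1", "level2"), ]
  td$signif <- dplyr::case_when(
    td$excludes_zero_95 ~ "95% excludes 0",
    td$excludes_zero_50 ~ "50% excludes 0",
    TRUE ~ "neither")
  td$covariate <- factor(td$covariate, levels = td$covariate)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$covariate)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_segment(ggplot2::aes(x = .data$conf.low,
                                       xend = .data$conf.high,
                                       yend = .data$covariate),
                          linewidth = 0.4) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$conf.low.50,
                                       xend = .data$conf.high.50,
                                       yend = .data$covariate),
                          linewidth = 1.1) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$signif), shape = 21,
                        size = 2.5) +
    ggplot2::scale_fill_manual(values = c("95% excludes 0" = "black",
                                          "50% excludes 0" = "gray60",
                                          "neither" = "white"),
                               name = NULL) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$level), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "standardized coefficient (posterior mean, 50% and 95% CrI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Posterior-predictive check plot
#'
#' @param object an `fgcm_ppc`.
#' @param ... unused.
#' @return A ggplot object showing the four Bayesian p-values against the
#'   0.05/0.95 misfit guides.
#' @export
autoplot.fgcm_ppc <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$check <- paste0("level ", df$level, " ", df$statistic)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$check, y = .data$p_value)) +
    ggplot2::geom_col(width = 0.5, fill = "gray40") +
    ggplot2::geom_hline(yintercept = c(0.05, 0.5, 0.95),
                        linetype = c("dashed", "dotted", "dashed")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Bayesian p-value") +
    ggplot2::theme_minimal()
}

#' Seasonal NDVI series plot
#'
#' @param seasonal tibble from [simulate_seasonal_covariates()].
#' @return A ggplot object with the mean and spatial-SD NDVI series.
#' @export
plot_seasonal <- function(seasonal) {
  long <- tidyr::pivot_longer(seasonal, c("ndvi_mean", "ndvi_sd"),
                              names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$series), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = "study day", y = "NDVI") +
    ggplot2::theme_minimal()
}
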