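#' Visual predictive check plot
#'
#' Simulated mean with percentile ribbon, optionally overlaid with
#' observed concentrations.
#'
#' @param ensemble A `simulation_ensemble` or a [summarize_vpc()] tibble.
#' @param observed Optional observed profile tibble (`time_h`,
#'   `conc_mg_L`); below-LLOQ rows are dropped.
#' @param log_y Plot the concentration axis on the log scale.
#' @return A ggplot object.
#' @export
plot_vpc <- function(ensemble, observed = NULL, log_y = FALSE) {
  bands <- if (inherits(ensemble, "simulation_ensemble")) {
    summarize_vpc(ensemble)
  } else {
    ensemble
  }
  p <- ggplot2::ggplot(bands, ggplot2::aes(x = .data$time_h)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conc_lo,
                                      ymax = .data$conc_hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$conc_mean),
                       color = "steelblue", linewidth = 0.8) +
    ggplot2::labs(x = "Time (h)", y = "Concentration (mg/L)",
                  title = "Predicted mean and 5th-95th percentile band")
  if (!is.null(observed)) {
    obs <- observed
    if ("blq" %in% names(obs)) obs <- obs[!obs$blq, ]
    p <- p + ggplot2::geom_point(data = obs,
                                 ggplot2::aes(y = .data$conc_mg_L),
                                 alpha = 0.6)
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.simulation_ensemble <- function(object, observed = NULL, ...) {
  plot_vpc(object, observed = observed, ...)
}

#' @exportS3Method ggplot2::autoplot
autoplot.lactation_study <- function(object, ...) {
  obs <- dplyr::filter(object$profiles, !.data$blq)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time_h, y = .data$conc_mg_L,
                                    group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~matrix, scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = "Concentration (mg/L)",
                  title = "Synthetic lactation study profiles")
}

#' Sensitivity-grid heat map
#'
#' @param grid Output of [sensitivity_grid()].
#' @param fill Which column to map to fill (`"mp_ratio"`, `"did"`,
#'   `"rid"`).
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(grid, fill = "mp_ratio") {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$ph_milk,
                                     y = .data$creamatocrit,
                                     fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Milk pH", y = "Creamatocrit (%)", fill = fill)
}
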