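#' Plot methods
#'
#' `autoplot()` methods for the package's result objects, plus thin
#' `plot_*()` wrappers. All return ggplot objects that can be further
#' customised.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name rwsens-plots
NULL

surface_long <- function(x, cols) {
  long <- tidy(x)
  tidyr::pivot_longer(long, dplyr::all_of(cols),
                      names_to = "surface", values_to = "value")
}

#' @rdname rwsens-plots
#' @method autoplot corr_grid
#' @export
autoplot.corr_grid <- function(object, ...) {
  df <- surface_long(object, c("rho_value", "rho_pe"))
  df$surface <- factor(df$surface, c("rho_value", "rho_pe"),
                       c("value", "prediction error"))
  ggplot2::ggplot(df, ggplot2::aes(.data$alpha_f, .data$alpha_g,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~surface) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "ρ") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = expression(alpha[f] ~ "(fit learning rate)"),
      y = expression(alpha[g] ~ "(true learning rate)"),
      title = sprintf("Regressor correlations, %s reward regime",
                      object$regime)
    )
}

#' @rdname rwsens-plots
#' @method autoplot t_grid
#' @export
autoplot.t_grid <- function(object, ...) {
  df <- surface_long(object, c("t_value", "t_pe"))
  df$surface <- factor(df$surface, c("t_value", "t_pe"),
                       c("value", "prediction error"))
  ggplot2::ggplot(df, ggplot2::aes(.data$alpha_f, .data$alpha_g,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~surface) +
    ggplot2::scale_fill_viridis_c(name = "t") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = expression(alpha[f]), y = expression(alpha[g]),
      title = sprintf("Expected t statistics (CNR=%g, T=%d)",
                      object$cnr, object$n_trials)
    )
}

#' @rdname rwsens-plots
#' @method autoplot loglik_profile
#' @export
autoplot.loglik_profile <- function(object, ...) {
  ggplot2::ggplot(dplyr::filter(object, .data$valid),
                  ggplot2::aes(.data$alpha, .data$delta_loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(object, "alpha_hat"),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(alpha), y = expression(Delta * "LL"),
                  title = "Log-likelihood profile over learning rates")
}

#' @rdname rwsens-plots
#' @method autoplot learner_trace
#' @export
autoplot.learner_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            c("reward", "value", "prediction_error"),
                            names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(.data$trial, .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trial", y = NULL,
                  title = sprintf("Learner trace (alpha = %g)",
                                  attr(object, "alpha")))
}

#' @rdname rwsens-plots
#' @param scan A tibble from [design_scan()].
#' @export
plot_design_scan <- function(scan, ...) {
  df <- tidyr::pivot_longer(scan, c("metric_value", "metric_pe"),
                            names_to = "surface", values_to = "metric")
  df$surface <- factor(df$surface, c("metric_value", "metric_pe"),
                       c("value", "prediction error"))
  ggplot2::ggplot(df, ggplot2::aes(.data$gamma, .data$drift_noise_ratio,
                                   fill = .data$metric)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~surface) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1),
                                  name = "insensitivity") +
    ggplot2::labs(x = expression(gamma),
                  y = expression(sigma[d] / sigma[n]),
                  title = "Insensitivity to learning rate across designs")
}

#' @rdname rwsens-plots
#' @param slice A tibble from [diagonal_slice()].
#' @param which `"pe"` or `"value"`.
#' @export
plot_diagonal_slice <- function(slice, which = c("pe", "value"), ...) {
  which <- match.arg(which)
  col <- if (which == "pe") "t_pe" else "t_value"
  df <- dplyr::filter(slice, .data$valid)
  df$t <- df[[col]]
  df$setting <- sprintf("CNR=%g, T=%d", df$cnr, df$n_trials)
  ggplot2::ggplot(df, ggplot2::aes(.data$d, .data$t,
                                   colour = .data$setting)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(alpha[g] - alpha[f]), y = "expected t",
                  title = sprintf("%s regressor, along alpha_g + alpha_f = const",
                                  which))
}
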