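#' Correlation surfaces over a learning-rate grid
#'
#' Evaluates the closed-form value and prediction-error correlations at
#' every pair of learning rates on a regular grid, for either reward
#' regime. The default fine grid (0.001 to 1 in steps of 0.001) matches
#' the resolution used for the correlation maps; coarser steps (e.g.
#' 0.01, the resolution used for the empirical analyses, or 0.05 for
#' quick sweeps) are substantially cheaper.
#'
#' @param regime `"fixed"` or `"drifting"`.
#' @param gamma,drift_noise_ratio Drifting-regime parameters (required
#'   when `regime = "drifting"`; ignored otherwise).
#' @param alpha_min,alpha_max,alpha_step Grid specification; learning
#'   rates must stay in `(0, 1]`.
#' @return A `corr_grid`: list with `alpha_grid`, matrices `rho_value`
#'   and `rho_pe` (rows index `alpha_g`, columns `alpha_f`), `regime`,
#'   `regime_params`. [tidy()] returns the long format
#'   (`alpha_g, alpha_f, rho_value, rho_pe`); [autoplot()] draws the two
#'   surfaces.
#' @examples
#' g <- corr_grid("fixed", alpha_step = 0.05)
#' min(g$rho_pe)       # >= 1/sqrt(2)
#' @export
corr_grid <- function(regime = c("fixed", "drifting"),
                      gamma = NULL, drift_noise_ratio = NULL,
                      alpha_min = 0.001, alpha_max = 1, alpha_step = 0.001) {
  regime <- match.arg(regime)
  if (alpha_min <= 0 || alpha_max > 1 || alpha_min > alpha_max) {
    abort("Require 0 < alpha_min <= alpha_max <= 1.")
  }
  alphas <- seq(alpha_min, alpha_max, by = alpha_step)
  if (regime == "drifting") {
    if (is.null(gamma) || is.null(drift_noise_ratio)) {
      abort("Drifting regime requires `gamma` and `drift_noise_ratio`.")
    }
    check_drift_params(gamma, drift_noise_ratio)
    rho_v <- outer(alphas, alphas, value_corr_drifting,
                   gamma = gamma, drift_noise_ratio = drift_noise_ratio)
    rho_pe <- outer(alphas, alphas, pe_corr_drifting,
                    gamma = gamma, drift_noise_ratio = drift_noise_ratio)
    params <- list(gamma = gamma, drift_noise_ratio = drift_noise_ratio)
  } else {
    rho_v <- outer(alphas, alphas, value_corr_fixed)
    rho_pe <- outer(alphas, alphas, pe_corr_fixed)
    params <- list()
  }
  structure(
    list(alpha_grid = alphas, rho_value = rho_v, rho_pe = rho_pe,
         regime = regime, regime_params = params),
    class = "corr_grid"
  )
}

#' @export
print.corr_grid <- function(x, ...) {
  extra <- if (x$regime == "drifting") {
    sprintf(" (gamma=%g, sd/sn=%g)", x$regime_params$gamma,
            x$regime_params$drift_noise_ratio)
  } else ""
  cat(sprintf(
    "<corr_grid> %s regime%s, %d x %d learning rates in [%g, %g]\n  rho_value in [%.4f, %.4f]; rho_pe in [%.4f, %.4f]\n",
    x$regime, extra, length(x$alpha_grid), length(x$alpha_grid),
    min(x$alpha_grid), max(x$alpha_grid),
    min(x$rho_value), max(x$rho_value), min(x$rho_pe), max(x$rho_pe)
  ))
  invisible(x)
}

#' @rdname corr_grid
#' @param x A `corr_grid`.
#' @param ... Unused.
#' @method tidy corr_grid
#' @export
tidy.corr_grid <- function(x, ...) {
  long <- tidyr::expand_grid(alpha_g = x$alpha_grid, alpha_f = x$alpha_grid)
  # expand_grid varies the last column fastest: row-major over (g, f),
  # matching t(matrix) flattening.
  long$rho_value <- as.vector(t(x$rho_value))
  long$rho_pe <- as.vector(t(x$rho_pe))
  long
}

#' Expected t statistics and significance masks over a correlation grid
#'
#' Applies the misspecified-regressor t formula ([expected_t()])
#' elementwise to a [corr_grid()], and thresholds the implied Student-t
#' p-values (`dof = n_trials - 2`) at `alpha_level`.
#'
#' @param grid A [corr_grid()].
#' @param cnr Contrast-to-noise ratio.
#' @param n_trials Number of data points `T >= 3`.
#' @param alpha_level Significance level for the masks (default 0.001, a
#'   common uncorrected threshold for single-subject effects).
#' @param tails `"two"` or `"one"` (see [p_from_t()]).
#' @return A `t_grid`: list with `alpha_grid`, matrices `t_value`,
#'   `t_pe`, `p_value`, `p_pe`, logical masks `sig_value`, `sig_pe`, and
#'   the parameters. [tidy()] returns the long format.
#' @export
t_grid <- function(grid, cnr, n_trials, alpha_level = 0.001,
                   tails = c("two", "one")) {
  stopifnot(inherits(grid, "corr_grid"))
  tails <- match.arg(tails)
  t_v <- expected_t(grid$rho_value, cnr, n_trials)
  t_pe <- expected_t(grid$rho_pe, cnr, n_trials)
  p_v <- p_from_t(t_v, n_trials - 2, tails)
  p_pe <- p_from_t(t_pe, n_trials - 2, tails)
  structure(
    list(alpha_grid = grid$alpha_grid,
         rho_value = grid$rho_value, rho_pe = grid$rho_pe,
         t_value = t_v, t_pe = t_pe,
         p_value_value = p_v, p_value_pe = p_pe,
         sig_value = p_v < alpha_level, sig_pe = p_pe < alpha_level,
         cnr = cnr, n_trials = n_trials, alpha_level = alpha_level,
         tails = tails, regime = grid$regime,
         regime_params = grid$regime_params),
    class = "t_grid"
  )
}

#' @export
print.t_grid <- function(x, ...) {
  cat(sprintf(
    "<t_grid> %s regime, CNR=%g, T=%d, %s-tailed p < %g\n  t_value in [%.3f, %.3f] (%.1f%% significant); t_pe in [%.3f, %.3f] (%.1f%% significant)\n",
    x$regime, x$cnr, x$n_trials, x$tails, x$alpha_level,
    min(x$t_value), max(x$t_value), 100 * mean(x$sig_value),
    min(x$t_pe), max(x$t_pe), 100 * mean(x$sig_pe)
  ))
  invisible(x)
}

#' @rdname t_grid
#' @param x A `t_grid`.
#' @param ... Unused.
#' @method tidy t_grid
#' @export
tidy.t_grid <- function(x, ...) {
  long <- tidyr::expand_grid(alpha_g = x$alpha_grid, alpha_f = x$alpha_grid)
  long$rho_value <- as.vector(t(x$rho_value))
  long$rho_pe <- as.vector(t(x$rho_pe))
  long$t_value <- as.vector(t(x$t_value))
  long$t_pe <- as.vector(t(x$t_pe))
  long$sig_value <- as.vector(t(x$sig_value))
  long$sig_pe <- as.vector(t(x$sig_pe))
  long
}

#' Insensitivity-to-learning-rate metric
#'
#' The fraction of learning-rate-pair space in which the regressor
#' correlation exceeds `threshold` (strictly). The metric is 1 when the
#' analysis barely depends on the fitted learning rate, 0 when it is
#' exquisitely sensitive.
#'
#' @param grid_surface Numeric matrix of correlations in `[-1, 1]` (e.g.
#'   `corr_grid(...)$rho_pe`).
#' @param threshold Correlation cutoff; cells exactly at the threshold do
#'   not count. Default 0.7.
#' @return A fraction in `[0, 1]`.
#' @examples
#' insensitivity_metric(corr_grid("fixed", alpha_step = 0.01)$rho_pe)  # 1
#' @export
insensitivity_metric <- function(grid_surface, threshold = 0.7) {
  m <- as.matrix(grid_surface)
  if (length(m) == 0) abort("Empty grid surface.")
  if (any(!is.finite(m)) || any(abs(m) > 1 + 1e-12)) {
    abort("Surface entries must be correlations in [-1, 1].")
  }
  mean(m > threshold)
}

#' Scan the design space of drifting-reward experiments
#'
#' Evaluates the insensitivity metric for the value and prediction-error
#' surfaces at every combination of the decay `gamma` and drift-to-noise
#' ratio — the two parameters an experimenter controls that determine
#' the correlation structure. The resulting maps show the trade-off
#' between sensitivity to value and to prediction-error regressors, and
#' can be used to pick reward dynamics before running an experiment.
#'
#' @param gamma_grid Decay values in `[0, 1)`; default spans 0.01–0.99.
#' @param ratio_grid Drift-to-noise ratios; default spans 0.1–5. A ratio
#'   of 0 reproduces the fixed-regime metrics exactly.
#' @param threshold Correlation cutoff for [insensitivity_metric()].
#' @param alpha_min,alpha_max,alpha_step Learning-rate grid on which each
#'   surface is evaluated (coarse 0.01 step by default: the scan is
#'   quadratic in the grid size).
#' @return A tibble: `gamma`, `drift_noise_ratio`, `metric_value`,
#'   `metric_pe`.
#' @export
design_scan <- function(gamma_grid = seq(0.01, 0.99, by = 0.07),
                        ratio_grid = seq(0.1, 5, length.out = 15),
                        threshold = 0.7,
                        alpha_min = 0.01, alpha_max = 1, alpha_step = 0.01) {
  cells <- tidyr::expand_grid(gamma = gamma_grid,
                              drift_noise_ratio = ratio_grid)
  alphas <- seq(alpha_min, alpha_max, by = alpha_step)
  metrics <- purrr::pmap(cells, function(gamma, drift_noise_ratio) {
    rv <- outer(alphas, alphas, value_corr_drifting,
                gamma = gamma, drift_noise_ratio = drift_noise_ratio)
    rp <- outer(alphas, alphas, pe_corr_drifting,
                gamma = gamma, drift_noise_ratio = drift_noise_ratio)
    tibble(metric_value = insensitivity_metric(rv, threshold),
           metric_pe = insensitivity_metric(rp, threshold))
  })
  dplyr::bind_cols(cells, dplyr::bind_rows(metrics))
}

#' Expected t statistics along a diagonal slice of the learning-rate grid
#'
#' Follows the constraint `alpha_g + alpha_f = s` (default `s = 1`, the
#' anti-diagonal) and reports the expected t statistic as a function of
#' the difference `d = alpha_g - alpha_f`, for every combination of the
#' supplied CNR and trial-count values. This is the one-dimensional view
#' that shows how the t statistic peaks at matched learning rates and how
#' the peak sharpens as CNR or `T` grows.
#'
#' Points whose implied learning rates fall outside `(0, 1]` are retained
#' with `valid = FALSE` and missing t values, preserving the grid shape.
#'
#' @param difference_grid Values of `d = alpha_g - alpha_f`; default
#'   -0.999 to 0.999 in steps of 0.001.
#' @param cnr,n_trials Vectors of design settings; all combinations are
#'   evaluated.
#' @param regime,gamma,drift_noise_ratio As in [corr_grid()].
#' @param s The fixed sum `alpha_g + alpha_f`.
#' @return A tibble: `cnr`, `n_trials`, `d`, `alpha_g`, `alpha_f`,
#'   `rho_value`, `rho_pe`, `t_value`, `t_pe`, `valid`.
#' @export
diagonal_slice <- function(difference_grid = seq(-0.999, 0.999, by = 0.001),
                           cnr = 1, n_trials = 50,
                           regime = c("fixed", "drifting"),
                           gamma = NULL, drift_noise_ratio = NULL,
                           s = 1.0) {
  regime <- match.arg(regime)
  base <- tidyr::expand_grid(cnr = cnr, n_trials = n_trials,
                             d = difference_grid)
  base$alpha_g <- (s + base$d) / 2
  base$alpha_f <- (s - base$d) / 2
  base$valid <- base$alpha_g > 0 & base$alpha_g <= 1 &
    base$alpha_f > 0 & base$alpha_f <= 1
  rho_v <- rho_p <- rep(NA_real_, nrow(base))
  ok <- base$valid
  if (regime == "fixed") {
    rho_v[ok] <- value_corr_fixed(base$alpha_g[ok], base$alpha_f[ok])
    rho_p[ok] <- pe_corr_fixed(base$alpha_g[ok], base$alpha_f[ok])
  } else {
    if (is.null(gamma) || is.null(drift_noise_ratio)) {
      abort("Drifting regime requires `gamma` and `drift_noise_ratio`.")
    }
    rho_v[ok] <- value_corr_drifting(base$alpha_g[ok], base$alpha_f[ok],
                                     gamma, drift_noise_ratio)
    rho_p[ok] <- pe_corr_drifting(base$alpha_g[ok], base$alpha_f[ok],
                                  gamma, drift_noise_ratio)
  }
  base$rho_value <- rho_v
  base$rho_pe <- rho_p
  t_v <- t_p <- rep(NA_real_, nrow(base))
  t_v[ok] <- expected_t(pmin(rho_v[ok], 1), base$cnr[ok], base$n_trials[ok])
  t_p[ok] <- expected_t(pmin(rho_p[ok], 1), base$cnr[ok], base$n_trials[ok])
  base$t_value <- t_v
  base$t_pe <- t_p
  base
}
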