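#' Closed-form regressor correlations across learning rates
#'
#' Correlation between the regressors produced by two Rescorla-Wagner
#' learners with learning rates `alpha_g` (ground truth) and `alpha_f`
#' (fit) observing the same reward stream, in the large-`T` limit.
#'
#' For a **fixed** reward distribution (any stationary distribution with
#' finite variance — the result does not depend on its mean or SD):
#' \deqn{\rho(V_g, V_f) = \frac{\sqrt{\alpha_g \alpha_f
#'   (2-\alpha_g)(2-\alpha_f)}}{\alpha_g + \alpha_f - \alpha_g\alpha_f}}
#' \deqn{\rho(\delta_g, \delta_f) = \frac{(\alpha_g+\alpha_f)
#'   \sqrt{(2-\alpha_g)(2-\alpha_f)}}{2(\alpha_g + \alpha_f -
#'   \alpha_g\alpha_f)}}
#' The prediction-error correlation is bounded below by
#' \eqn{1/\sqrt{2} \approx 0.71}, approached as one learning rate tends
#' to 0 and the other to 1.
#'
#' For a **drifting** reward distribution (latent mean a mean-reverting
#' random walk with decay `gamma`, drift SD \eqn{\sigma_d}, observation
#' noise SD \eqn{\sigma_n}) the correlations depend only on `gamma` and
#' the drift-to-noise ratio \eqn{\sigma_d/\sigma_n}. With
#' \eqn{h_i = 1/(1-\gamma+\alpha_i\gamma)},
#' \eqn{D = \sigma_d^2/((1-\gamma^2)\sigma_n^2)} and
#' \eqn{q = \sigma_d^2/((1+\gamma)\sigma_n^2)}, the forms obtained by
#' geometric-series summation of the moment machinery are
#' \deqn{\rho(V_g,V_f) = \frac{\frac{\alpha_g\alpha_f}{S}\,(1 + D(h_g+h_f-1))}
#'   {\sqrt{\frac{\alpha_g}{2-\alpha_g}(1 + D(2h_g-1))\;
#'          \frac{\alpha_f}{2-\alpha_f}(1 + D(2h_f-1))}}}
#' \deqn{\rho(\delta_g,\delta_f) =
#'   \frac{\big((\alpha_g+\alpha_f) + (\alpha_g h_g + \alpha_f h_f)\,q\big)
#'   \sqrt{(2-\alpha_g)(2-\alpha_f)}}
#'   {2S\sqrt{(1 + h_g q)(1 + h_f q)}}}
#' with \eqn{S = \alpha_g + \alpha_f - \alpha_g\alpha_f}. At
#' `drift_noise_ratio = 0` both reduce exactly to the fixed-reward forms.
#'
#' All four functions are vectorised over their arguments, symmetric in
#' `(alpha_g, alpha_f)`, and equal to 1 on the diagonal.
#'
#' @param alpha_g,alpha_f Learning rates in `(0, 1]`; vectors recycled.
#' @param gamma Decay of the latent reward mean per trial, in `[0, 1)`.
#' @param drift_noise_ratio \eqn{\sigma_d/\sigma_n \ge 0}.
#' @return Correlation(s) in `(0, 1]`.
#' @examples
#' value_corr_fixed(0.1, 0.9)              # ~0.477
#' pe_corr_fixed(0.1, 0.9)                 # ~0.794
#' value_corr_drifting(0.1, 0.9, gamma = 0.98, drift_noise_ratio = 0.7)
#' @name analytic_correlations
NULL

check_alpha_grid <- function(alpha_g, alpha_f) {
  if (any(!is.finite(alpha_g)) || any(!is.finite(alpha_f)) ||
      any(alpha_g <= 0) || any(alpha_f <= 0) ||
      any(alpha_g > 1) || any(alpha_f > 1)) {
    abort("Learning rates must lie in (0, 1].")
  }
}

check_drift_params <- function(gamma, drift_noise_ratio) {
  if (any(gamma < 0) || any(gamma >= 1)) {
    abort("`gamma` must lie in [0, 1): no stationary process otherwise.")
  }
  if (any(drift_noise_ratio < 0)) {
    abort("`drift_noise_ratio` must be >= 0.")
  }
}

#' @rdname analytic_correlations
#' @export
value_corr_fixed <- function(alpha_g, alpha_f) {
  check_alpha_grid(alpha_g, alpha_f)
  s <- alpha_g + alpha_f - alpha_g * alpha_f
  clamp_unit(sqrt(alpha_g * alpha_f * (2 - alpha_g) * (2 - alpha_f)) / s)
}

#' @rdname analytic_correlations
#' @export
pe_corr_fixed <- function(alpha_g, alpha_f) {
  check_alpha_grid(alpha_g, alpha_f)
  s <- alpha_g + alpha_f - alpha_g * alpha_f
  clamp_unit((alpha_g + alpha_f) * sqrt((2 - alpha_g) * (2 - alpha_f)) / (2 * s))
}

#' @rdname analytic_correlations
#' @export
value_corr_drifting <- function(alpha_g, alpha_f, gamma, drift_noise_ratio) {
  check_alpha_grid(alpha_g, alpha_f)
  check_drift_params(gamma, drift_noise_ratio)
  d <- drift_noise_ratio^2 / (1 - gamma^2)
  h_g <- 1 / (1 - gamma + alpha_g * gamma)
  h_f <- 1 / (1 - gamma + alpha_f * gamma)
  s <- alpha_g + alpha_f - alpha_g * alpha_f
  cov_ij <- alpha_g * alpha_f / s * (1 + d * (h_g + h_f - 1))
  var_g <- alpha_g / (2 - alpha_g) * (1 + d * (2 * h_g - 1))
  var_f <- alpha_f / (2 - alpha_f) * (1 + d * (2 * h_f - 1))
  clamp_unit(cov_ij / sqrt(var_g * var_f))
}

#' @rdname analytic_correlations
#' @export
pe_corr_drifting <- function(alpha_g, alpha_f, gamma, drift_noise_ratio) {
  check_alpha_grid(alpha_g, alpha_f)
  check_drift_params(gamma, drift_noise_ratio)
  q <- drift_noise_ratio^2 / (1 + gamma)
  h_g <- 1 / (1 - gamma + alpha_g * gamma)
  h_f <- 1 / (1 - gamma + alpha_f * gamma)
  s <- alpha_g + alpha_f - alpha_g * alpha_f
  num <- (alpha_g + alpha_f) + (alpha_g * h_g + alpha_f * h_f) * q
  clamp_unit(num * sqrt((2 - alpha_g) * (2 - alpha_f)) /
    (2 * s * sqrt((1 + h_g * q) * (1 + h_f * q))))
}

# The closed forms are analytically in (0, 1]; floating-point evaluation can
# overshoot 1 by a few ulp on the diagonal. Clamp that overshoot only.
clamp_unit <- function(rho) {
  stopifnot(all(rho <= 1 + 1e-12))
  pmin(rho, 1)
}
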