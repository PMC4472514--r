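#' Expected regression results under a misspecified regressor
#'
#' Suppose the measured signal is \eqn{Y = \beta x_g + \epsilon} with
#' white Gaussian noise of SD \eqn{\sigma_{fMRI}}, but the analysis
#' regresses `Y` on a different regressor \eqn{x_f} (same model, wrong
#' parameter). If both regressors are normalized to unit (population)
#' variance, then in expectation:
#'
#' * the fitted coefficient is attenuated to \eqn{\hat\beta = \beta\rho},
#'   where \eqn{\rho = \rho(x_g, x_f)} ([expected_beta_hat()]);
#' * the residual SD is \eqn{\sqrt{\sigma_{fMRI}^2 + \beta^2(1-\rho^2)}},
#'   the unexplained share of the signal joining the noise
#'   ([expected_residual_sd()]);
#' * the Student t statistic is
#'   \deqn{\hat t = \frac{\rho\,\mathrm{CNR}\,\sqrt{T-2}}
#'     {\sqrt{1 + \mathrm{CNR}^2 (1-\rho^2)}}}
#'   where \eqn{\mathrm{CNR} = \beta/\sigma_{fMRI}} is the
#'   contrast-to-noise ratio ([expected_t()]).
#'
#' At low CNR, \eqn{\hat t \approx \rho\,\mathrm{CNR}\sqrt{T-2}}: the t
#' statistic is simply proportional to the regressor correlation.
#'
#' @param beta True effect size (signal units).
#' @param rho Correlation between the true and the fitted regressor, in
#'   `[-1, 1]`.
#' @param sigma_fmri Measurement noise SD (signal units), `> 0`.
#' @param cnr Contrast-to-noise ratio `beta / sigma_fmri`, unitless.
#' @param n_trials Number of data points `T >= 3` in the regression.
#' @return A numeric vector (all functions are vectorised).
#' @examples
#' expected_beta_hat(2, 0.7071)     # ~1.414
#' expected_t(1 / sqrt(2), cnr = 1, n_trials = 50)  # ~4.0
#' @name regression_theory
NULL

check_rho <- function(rho) {
  if (any(!is.finite(rho)) || any(abs(rho) > 1)) {
    abort("`rho` must lie in [-1, 1].")
  }
}

#' @rdname regression_theory
#' @export
expected_beta_hat <- function(beta, rho) {
  check_rho(rho)
  beta * rho
}

#' @rdname regression_theory
#' @export
expected_residual_sd <- function(beta, sigma_fmri, rho) {
  check_rho(rho)
  if (any(sigma_fmri <= 0)) abort("`sigma_fmri` must be > 0.")
  sqrt(sigma_fmri^2 + beta^2 * (1 - rho^2))
}

#' @rdname regression_theory
#' @export
expected_t <- function(rho, cnr, n_trials) {
  check_rho(rho)
  if (any(n_trials < 3)) abort("`n_trials` must be >= 3.")
  rho * cnr * sqrt(n_trials - 2) / sqrt(1 + cnr^2 * (1 - rho^2))
}

#' Student-t tail probability of a t statistic
#'
#' @param t Observed t statistic(s).
#' @param dof Degrees of freedom, `>= 1`.
#' @param tails `"two"` (default, conservative) or `"one"`.
#' @return p-value(s), monotone decreasing in `|t|`.
#' @examples
#' p_from_t(4.0, dof = 48)   # ~2.2e-4
#' @export
p_from_t <- function(t, dof, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (any(dof < 1)) abort("`dof` must be >= 1.")
  p <- pt(abs(t), df = dof, lower.tail = FALSE)
  if (tails == "two") 2 * p else p
}

#' Gaussian maximum-likelihood log-likelihood of a regression fit
#'
#' For a linear model whose residuals have population SD
#' \eqn{\sigma_r} (divisor-`T` convention), the maximised Gaussian
#' log-likelihood is
#' \deqn{LL = -T\big(\log(\sqrt{2\pi}\,\sigma_r) + \tfrac12\big).}
#' Only differences \eqn{\Delta LL} between fits are meaningful
#' downstream, so the additive constant merely needs to be consistent;
#' doubling \eqn{\sigma_r} lowers `LL` by exactly \eqn{T\log 2}.
#'
#' @param residual_sd Population (divisor-`T`) SD of the residuals, `> 0`.
#' @param n_trials Number of data points `T`.
#' @return The log-likelihood (a scalar per input element; vectorised).
#' @export
gaussian_loglik <- function(residual_sd, n_trials) {
  if (any(residual_sd <= 0)) abort("`residual_sd` must be > 0.")
  if (any(n_trials < 1)) abort("`n_trials` must be >= 1.")
  -n_trials * (log(sqrt(2 * pi) * residual_sd) + 0.5)
}
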