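#' Large-T moments of value regressors for a pair of learning rates
#'
#' Computes the approximate mean, variances and covariance of the value
#' regressors \eqn{V_i, V_j} produced by Rescorla-Wagner learners with
#' learning rates `alpha_i`, `alpha_j` on a shared reward stream whose
#' statistics are given by a [reward_stats()] object:
#' \deqn{\mu(V_i) \approx \mu(r)}
#' \deqn{\sigma(V_i)^2 \approx \frac{\alpha_i}{2-\alpha_i}\Big(\mu(r^2) +
#'   \frac{2}{T}\sum_{\Delta=1}^{T-1} (T-\Delta)(1-\alpha_i)^\Delta
#'   R_\Delta(r)\Big) - \mu(r)^2}
#' \deqn{\mathrm{cov}(V_i,V_j) \approx
#'   \frac{\alpha_i\alpha_j}{\alpha_i+\alpha_j-\alpha_i\alpha_j}
#'   \Big(\mu(r^2) + \frac{1}{T}\sum_{\Delta=1}^{T-1}
#'   \big((1-\alpha_i)^\Delta + (1-\alpha_j)^\Delta\big)(T-\Delta)
#'   R_\Delta(r)\Big) - \mu(r)^2}
#' The approximations drop initial-condition transients and hold when `T`
#' is large relative to `1/alpha`; a warning is issued when
#' `n_trials * min(alpha) < 10`.
#'
#' Two evaluation methods are provided and must agree: `"direct_sum"`
#' evaluates the lag sums literally in O(T); `"geometric"` uses exact
#' finite-sum closed forms, available because both supported reward
#' processes have geometric autocorrelation \eqn{R_\Delta = c\,g^\Delta}
#' (a fixed distribution has \eqn{g = 1}).
#'
#' @param alpha_i,alpha_j Learning rates in `(0, 1]`.
#' @param stats A [reward_stats()] object.
#' @param n_trials Number of trials `T` entering the lag sums.
#' @param method `"direct_sum"` or `"geometric"`.
#' @return A `moment_set`: list with `mean_i`, `mean_j`, `var_i`, `var_j`,
#'   `cov_ij`, `n_trials`, `alphas`, `kind`.
#' @seealso [pe_moments()], [corr_from_moments()]
#' @export
value_moments <- function(alpha_i, alpha_j, stats, n_trials,
                          method = c("direct_sum", "geometric")) {
  method <- match.arg(method)
  check_moment_args(alpha_i, alpha_j, stats, n_trials)
  # W_i = sum_{Delta=1}^{T-1} (T - Delta) (1 - alpha_i)^Delta R_Delta(r)
  w_i <- value_lag_sum(alpha_i, stats, n_trials, method)
  w_j <- value_lag_sum(alpha_j, stats, n_trials, method)
  s <- alpha_i + alpha_j - alpha_i * alpha_j
  var_i <- alpha_i / (2 - alpha_i) *
    (stats$mu_r2 + 2 / n_trials * w_i) - stats$mu_r^2
  var_j <- alpha_j / (2 - alpha_j) *
    (stats$mu_r2 + 2 / n_trials * w_j) - stats$mu_r^2
  cov_ij <- alpha_i * alpha_j / s *
    (stats$mu_r2 + (w_i + w_j) / n_trials) - stats$mu_r^2
  new_moment_set(stats$mu_r, stats$mu_r, var_i, var_j, cov_ij,
                 n_trials, c(alpha_i, alpha_j), kind = "value")
}

#' Large-T moments of prediction-error regressors
#'
#' The prediction-error counterpart of [value_moments()]:
#' \deqn{\mu(\delta_i) \approx 0}
#' \deqn{\sigma(\delta_i)^2 \approx \frac{2}{2-\alpha_i}\Big(\mu(r^2) -
#'   \sum_{\Delta=1}^{T-1} \alpha_i (1-\alpha_i)^{\Delta-1}
#'   \big(1 - \tfrac{\Delta}{T}\big) R_\Delta(r)\Big)}
#' \deqn{\mathrm{cov}(\delta_i,\delta_j) \approx
#'   \frac{1}{\alpha_i+\alpha_j-\alpha_i\alpha_j}
#'   \Big((\alpha_i+\alpha_j)\mu(r^2) - \sum_{\Delta=1}^{T-1}
#'   \big(\alpha_i^2(1-\alpha_i)^{\Delta-1} +
#'   \alpha_j^2(1-\alpha_j)^{\Delta-1}\big)
#'   \big(1 - \tfrac{\Delta}{T}\big) R_\Delta(r)\Big)}
#'
#' @inheritParams value_moments
#' @return A `moment_set` (means are 0 by the large-T approximation).
#' @export
pe_moments <- function(alpha_i, alpha_j, stats, n_trials,
                       method = c("direct_sum", "geometric")) {
  method <- match.arg(method)
  check_moment_args(alpha_i, alpha_j, stats, n_trials)
  # U_i = sum_{Delta} alpha_i (1-alpha_i)^(Delta-1) (1 - Delta/T) R_Delta
  u_i <- pe_lag_sum(alpha_i, stats, n_trials, method)
  u_j <- pe_lag_sum(alpha_j, stats, n_trials, method)
  s <- alpha_i + alpha_j - alpha_i * alpha_j
  var_i <- 2 / (2 - alpha_i) * (stats$mu_r2 - u_i)
  var_j <- 2 / (2 - alpha_j) * (stats$mu_r2 - u_j)
  cov_ij <- ((alpha_i + alpha_j) * stats$mu_r2 -
               alpha_i * u_i - alpha_j * u_j) / s
  new_moment_set(0, 0, var_i, var_j, cov_ij,
                 n_trials, c(alpha_i, alpha_j), kind = "prediction_error")
}

#' Correlation implied by a moment set
#'
#' \eqn{\rho = \mathrm{cov}_{ij} / \sqrt{\mathrm{var}_i\,\mathrm{var}_j}},
#' clamped to `[-1, 1]`. Clamping only ever corrects floating-point
#' overshoot; a pre-clamp violation larger than `1e-8` is reported via a
#' warning, smaller ones via a message, so silent Cauchy-Schwarz
#' violations cannot occur.
#'
#' @param m A `moment_set` from [value_moments()] or [pe_moments()].
#' @return A single correlation in `[-1, 1]`.
#' @export
corr_from_moments <- function(m) {
  stopifnot(inherits(m, "moment_set"))
  if (m$var_i <= 0 || m$var_j <= 0) {
    abort("Correlation undefined: a regressor variance is not positive.")
  }
  rho <- m$cov_ij / sqrt(m$var_i * m$var_j)
  if (abs(rho) > 1) {
    excess <- abs(rho) - 1
    if (excess > 1e-8) {
      warn(sprintf("Correlation %.12f clamped to [-1, 1] (excess %.3g).",
                   rho, excess))
    } else {
      message(sprintf("Correlation clamped to [-1, 1] (excess %.3g).", excess))
    }
    rho <- sign(rho)
  }
  rho
}

#' @export
print.moment_set <- function(x, ...) {
  cat(sprintf(
    "<moment_set: %s> alphas=(%g, %g), T=%g\n  means=(%g, %g) vars=(%g, %g) cov=%g\n",
    x$kind, x$alphas[1], x$alphas[2], x$n_trials,
    x$mean_i, x$mean_j, x$var_i, x$var_j, x$cov_ij
  ))
  invisible(x)
}

#' @rdname value_moments
#' @param x A `moment_set`.
#' @param ... Unused.
#' @method tidy moment_set
#' @export
tidy.moment_set <- function(x, ...) {
  tibble(
    kind = x$kind,
    alpha_i = x$alphas[1], alpha_j = x$alphas[2], n_trials = x$n_trials,
    mean_i = x$mean_i, mean_j = x$mean_j,
    var_i = x$var_i, var_j = x$var_j, cov_ij = x$cov_ij
  )
}

new_moment_set <- function(mean_i, mean_j, var_i, var_j, cov_ij,
                           n_trials, alphas, kind) {
  structure(
    list(mean_i = mean_i, mean_j = mean_j, var_i = var_i, var_j = var_j,
         cov_ij = cov_ij, n_trials = n_trials, alphas = alphas, kind = kind),
    class = "moment_set"
  )
}

check_moment_args <- function(alpha_i, alpha_j, stats, n_trials) {
  ok <- function(a) is.numeric(a) && length(a) == 1L && is.finite(a) &&
    a > 0 && a <= 1
  if (!ok(alpha_i) || !ok(alpha_j)) {
    abort("Learning rates must be single numbers in (0, 1].")
  }
  stopifnot(inherits(stats, "reward_stats"))
  if (n_trials < 2) abort("`n_trials` must be at least 2.")
  if (n_trials * min(alpha_i, alpha_j) < 10) {
    warn(paste(
      "n_trials * min(alpha) < 10: the large-T approximation may be poor;",
      "interpret with caution."
    ))
  }
}

# sum_{Delta=1}^{T-1} (T - Delta) x^Delta * R_Delta with R_Delta = c g^Delta
value_lag_sum <- function(alpha, stats, n_trials, method) {
  if (method == "direct_sum") {
    delta <- seq_len(n_trials - 1)
    sum((n_trials - delta) * (1 - alpha)^delta * stats$autocorr(delta))
  } else {
    x <- (1 - alpha) * stats$ac_decay
    n <- n_trials - 1
    stats$ac_scale * (n_trials * geom_sum(x, n) - geom_sum_delta(x, n))
  }
}

# sum_{Delta=1}^{T-1} alpha (1-alpha)^(Delta-1) (1 - Delta/T) R_Delta
pe_lag_sum <- function(alpha, stats, n_trials, method) {
  if (method == "direct_sum") {
    delta <- seq_len(n_trials - 1)
    sum(alpha * (1 - alpha)^(delta - 1) * (1 - delta / n_trials) *
          stats$autocorr(delta))
  } else {
    # R_Delta = c g^Delta so the summand is alpha * c * g * x^(Delta-1)
    # with x = (1 - alpha) g.
    x <- (1 - alpha) * stats$ac_decay
    n <- n_trials - 1
    alpha * stats$ac_scale * stats$ac_decay *
      (geom_sum0(x, n) - geom_sum_dx(x, n) / n_trials)
  }
}

# sum_{k=1}^{n} x^k
geom_sum <- function(x, n) {
  if (x == 1) return(n)
  x * (1 - x^n) / (1 - x)
}

# sum_{k=0}^{n-1} x^k
geom_sum0 <- function(x, n) {
  if (x == 1) return(n)
  (1 - x^n) / (1 - x)
}

# sum_{k=1}^{n} k x^k
geom_sum_delta <- function(x, n) {
  if (x == 1) return(n * (n + 1) / 2)
  x * (1 - (n + 1) * x^n + n * x^(n + 1)) / (1 - x)^2
}

# sum_{k=1}^{n} k x^(k-1)
geom_sum_dx <- function(x, n) {
  if (x == 1) return(n * (n + 1) / 2)
  (1 - (n + 1) * x^n + n * x^(n + 1)) / (1 - x)^2
}
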