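#' Generate a synthetic signal from ground-truth regressors
#'
#' Builds \eqn{Y = \sum_k \beta_k x_k + \epsilon} with i.i.d. Gaussian
#' noise \eqn{\epsilon \sim N(0, \sigma_{fMRI}^2)}. This is the
#' generative model under which the misspecified-regressor theory is
#' exact, and the workhorse for validating it by simulation.
#'
#' @param regressors Numeric matrix or data frame (`T` rows, `k`
#'   ground-truth columns). A `trial` column, if present, is dropped.
#' @param betas Numeric vector of length `k`, true effect sizes.
#' @param sigma_fmri Noise SD, `>= 0`.
#' @param seed Integer seed (required).
#' @return Numeric signal vector of length `T`.
#' @export
generate_signal <- function(regressors, betas, sigma_fmri, seed) {
  x <- as_design_matrix(regressors)
  if (length(betas) != ncol(x)) {
    abort(sprintf("Length of `betas` (%d) must match the number of regressor columns (%d).",
                  length(betas), ncol(x)))
  }
  if (sigma_fmri < 0) abort("`sigma_fmri` must be >= 0.")
  check_sampling_args(nrow(x), seed)
  noise <- if (sigma_fmri == 0) 0 else {
    with_seed(seed, rnorm(nrow(x), 0, sigma_fmri))
  }
  as.numeric(x %*% betas + noise)
}

as_design_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[setdiff(names(x), "trial")]
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) abort("Regressor columns must be finite.")
  x
}

#' Fit an ordinary least squares model
#'
#' Solves the normal equations for `signal ~ design` (QR decomposition,
#' via [stats::lm.fit()]) and packages the quantities the sensitivity
#' theory consumes. The design matrix should already contain an intercept
#' column (named `(Intercept)` by [with_intercept()]).
#'
#' Conventions: `dof = T - k`; standard errors use the unbiased residual
#' variance (divisor `T - k`), so `t_stats = coefficients /
#' standard_errors` are ordinary regression t statistics; `residual_sd`
#' is the *population* (divisor `T`) SD of the residuals, the convention
#' the Gaussian log-likelihood uses; `loglik` is [gaussian_loglik()] of
#' that SD.
#'
#' @param signal Numeric response vector.
#' @param design Numeric matrix (or data frame) with named columns,
#'   including an intercept column; must have full column rank.
#' @return A `glm_result`: list with `coefficients`, `standard_errors`,
#'   `t_stats`, `residual_sd`, `dof`, `loglik`, `n_trials`, `residuals`.
#'   [tidy()] gives a per-term tibble, [glance()] a one-row summary.
#' @examples
#' x <- rnorm(60)
#' y <- 2 * x + rnorm(60)
#' fit <- fit_ols(y, with_intercept(x = x))
#' tidy(fit)
#' @export
fit_ols <- function(signal, design) {
  x <- as_design_matrix(design)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (!is.numeric(signal) || length(signal) != nrow(x)) {
    abort("`signal` must be numeric with one value per design row.")
  }
  n <- nrow(x)
  k <- ncol(x)
  if (n <= k) abort("Need more observations than design columns.")
  qrx <- qr(x)
  if (qrx$rank < k) {
    bad <- colnames(x)[qrx$pivot[(qrx$rank + 1):k]]
    abort(sprintf("Design matrix is rank deficient; collinear column(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  fit <- lm.fit(x, signal)
  res <- fit$residuals
  rss <- sum(res^2)
  sigma2_unbiased <- rss / (n - k)
  xtx_inv <- chol2inv(chol(crossprod(x)))
  se <- sqrt(sigma2_unbiased * diag(xtx_inv))
  names(se) <- colnames(x)
  coefs <- fit$coefficients[colnames(x)]
  residual_sd <- sqrt(rss / n)
  structure(
    list(
      coefficients = coefs,
      standard_errors = se,
      t_stats = coefs / se,
      residual_sd = residual_sd,
      dof = n - k,
      loglik = if (residual_sd > 0) gaussian_loglik(residual_sd, n) else Inf,
      n_trials = n,
      residuals = res
    ),
    class = "glm_result"
  )
}

#' Prepend an intercept column to regressors
#'
#' @param ... Named numeric vectors (or a single matrix/data frame) to
#'   bind as design columns after the intercept.
#' @return A numeric matrix whose first column, `(Intercept)`, is all 1s.
#' @export
with_intercept <- function(...) {
  args <- list(...)
  x <- if (length(args) == 1L && (is.matrix(args[[1]]) || is.data.frame(args[[1]]))) {
    as_design_matrix(args[[1]])
  } else {
    do.call(cbind, args)
  }
  cbind(`(Intercept)` = 1, x)
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("<glm_result> T=%d, dof=%d, residual_sd=%.4g, loglik=%.4g\n",
              x$n_trials, x$dof, x$residual_sd, x$loglik))
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_ols
#' @param x A `glm_result`.
#' @param ... Unused.
#' @method tidy glm_result
#' @export
tidy.glm_result <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(x$standard_errors),
    statistic = unname(x$t_stats),
    p.value = p_from_t(unname(x$t_stats), x$dof)
  )
}

#' @rdname fit_ols
#' @method glance glm_result
#' @export
glance.glm_result <- function(x, ...) {
  tibble(
    n_trials = x$n_trials,
    dof = x$dof,
    residual_sd = x$residual_sd,
    logLik = x$loglik
  )
}

#' Log-likelihood profile over a learning-rate grid
#'
#' For each candidate learning rate, builds normalized model-based
#' regressor(s) from the reward sequence, fits an OLS model (with
#' intercept) to the signal, and evaluates the Gaussian log-likelihood of
#' the fit. Profiles are reported relative to their maximum,
#' \eqn{\Delta LL(\alpha) = LL(\alpha) - \max_\alpha LL(\alpha)}, so the
#' maximum of the output is exactly 0. The sharpness of the profile is
#' what determines whether the learning rate can be recovered from the
#' signal: at high contrast-to-noise ratio profiles are sharply peaked
#' near the generating value, at low CNR they are nearly flat.
#'
#' Candidate learning rates at which a regressor is degenerate (zero
#' variance) are kept in the output with `valid = FALSE` and missing
#' log-likelihood, never silently dropped. Ties in the argmax are broken
#' towards the smallest learning rate (and reported via a message).
#'
#' @param signal Numeric signal vector (length `T`).
#' @param rewards Reward sequence (vector or tibble with `reward`), same
#'   length.
#' @param alpha_grid Candidate learning rates in `(0, 1]`.
#' @param which Which regressor(s) to include: `"value"`, `"pe"`, or
#'   `"both"`.
#' @param v_init Initial value passed to [simulate_learner()].
#' @return A `loglik_profile` tibble with columns `alpha`, `loglik`,
#'   `delta_loglik`, `valid`, and attributes `alpha_hat` (the argmax) and
#'   `which`.
#' @export
loglik_profile <- function(signal, rewards, alpha_grid,
                           which = c("value", "pe", "both"), v_init = 0) {
  which <- match.arg(which)
  r <- as_reward_vector(rewards)
  stopifnot(length(signal) == length(r))
  if (any(alpha_grid <= 0) || any(alpha_grid > 1)) {
    abort("`alpha_grid` must lie in (0, 1].")
  }
  ll <- purrr::map_dbl(alpha_grid, function(a) {
    trace <- simulate_learner(r, a, v_init)
    regs <- tryCatch(build_regressors(trace, normalize = TRUE),
                     error = function(e) NULL)
    if (is.null(regs)) return(NA_real_)
    design <- switch(which,
      value = with_intercept(value = regs$value),
      pe = with_intercept(prediction_error = regs$prediction_error),
      both = with_intercept(value = regs$value,
                            prediction_error = regs$prediction_error)
    )
    fit_ols(signal, design)$loglik
  })
  valid <- is.finite(ll)
  if (!any(valid)) abort("No valid grid point: all regressors degenerate.")
  best <- max(ll[valid])
  winners <- which(valid & abs(ll - best) < 1e-12)
  if (length(winners) > 1) {
    message(sprintf("Log-likelihood tie among %d grid points; smallest alpha (%g) reported.",
                    length(winners), alpha_grid[min(winners)]))
  }
  out <- tibble(
    alpha = alpha_grid,
    loglik = ll,
    delta_loglik = ll - best,
    valid = valid
  )
  structure(out, alpha_hat = alpha_grid[min(winners)], which = which,
            class = c("loglik_profile", class(out)))
}

#' Random-effects group t test of per-subject coefficients
#'
#' One-sample Student t test of `n` per-subject regression coefficients
#' against zero — the standard random-effects group analysis.
#'
#' @param per_subject_betas Numeric vector, one coefficient per subject
#'   (`n >= 2`).
#' @return A list with `group_t`, `dof = n - 1`, `p_value` (two-tailed)
#'   and `mean_beta`.
#' @export
group_ttest <- function(per_subject_betas) {
  b <- per_subject_betas
  if (!is.numeric(b) || length(b) < 2) abort("Need at least 2 subjects.")
  if (sd(b) == 0) {
    abort("Per-subject coefficients have zero variance: the group t statistic is undefined.")
  }
  tt <- t.test(b, mu = 0)
  list(
    group_t = unname(tt$statistic),
    dof = length(b) - 1L,
    p_value = tt$p.value,
    mean_beta = mean(b)
  )
}

#' Best/worst-case group envelope over a learning-rate grid
#'
#' For each subject, selects the grid column that maximises
#' (respectively minimises) that subject's curve, then applies the group
#' test to the selected values. This brackets how far per-subject cherry
#' picking of the learning rate could move the group statistic: by
#' construction the selected per-subject values dominate (are dominated
#' by) the value at any common learning rate.
#'
#' @param per_subject_curves Numeric matrix, one row per subject, one
#'   column per grid learning rate (the per-subject coefficient or t
#'   curves); at least one column.
#' @return A tibble with rows `best` and `worst`: `case`,
#'   `mean_selected`, `group_t`, `dof`, `p_value`.
#' @export
best_worst_envelope <- function(per_subject_curves) {
  m <- as.matrix(per_subject_curves)
  if (ncol(m) < 1 || nrow(m) < 2) {
    abort("Need a matrix with >= 2 subjects and >= 1 grid point.")
  }
  best <- apply(m, 1, max)
  worst <- apply(m, 1, min)
  gb <- group_ttest(best)
  gw <- group_ttest(worst)
  tibble(
    case = c("best", "worst"),
    mean_selected = c(gb$mean_beta, gw$mean_beta),
    group_t = c(gb$group_t, gw$group_t),
    dof = c(gb$dof, gw$dof),
    p_value = c(gb$p_value, gw$p_value)
  )
}
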