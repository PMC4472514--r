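# Simulation oracles shared across test files. These deliberately avoid the
# package's closed-form code paths: correlations come from cor() on simulated
# traces, regression results from repeated OLS fits, so closed forms and
# simulation stay independent routes to the same quantity.

# Empirical correlation of value / prediction-error traces for two learning
# rates sharing one reward stream, transients discarded.
empirical_trace_corr <- function(rewards, alpha_g, alpha_f, burn_in = 1000) {
  tr_g <- simulate_learner(rewards, alpha_g)
  tr_f <- simulate_learner(rewards, alpha_f)
  keep <- seq(burn_in + 1, length(tr_g$value))
  c(
    value = cor(tr_g$value[keep], tr_f$value[keep]),
    pe = cor(tr_g$prediction_error[keep], tr_f$prediction_error[keep])
  )
}

# Hand-rolled RW iteration (the definitional loop, not the filter-based
# implementation) for cross-checking simulate_learner.
rw_loop_oracle <- function(rewards, alpha, v_init = 0) {
  n <- length(rewards)
  v <- numeric(n)
  pe <- numeric(n)
  v[1] <- v_init
  for (t in seq_len(n)) {
    pe[t] <- rewards[t] - v[t]
    if (t < n) v[t + 1] <- v[t] + alpha * pe[t]
  }
  list(values = v, prediction_errors = pe)
}

# Mean fitted coefficient and t statistic of Y = beta * x_g + noise fitted
# against x_f (with intercept), over n_rep independent noise draws.
ols_replicate_oracle <- function(x_g, x_f, beta, sigma, n_rep, seed) {
  res <- withr::with_seed(seed, {
    vapply(seq_len(n_rep), function(i) {
      y <- beta * x_g + rnorm(length(x_g), 0, sigma)
      fit <- fit_ols(y, with_intercept(xf = x_f))
      c(fit$coefficients[["xf"]], fit$t_stats[["xf"]])
    }, numeric(2))
  })
  list(
    beta_hat = res[1, ], t_hat = res[2, ],
    mean_beta = mean(res[1, ]), se_beta = sd(res[1, ]) / sqrt(n_rep),
    mean_t = mean(res[2, ]), se_t = sd(res[2, ]) / sqrt(n_rep)
  )
}

# Normalized ground-truth regressors from a reward stream, plus the sample
# correlation between the two candidate regressors (the in-sample rho that
# the attenuation identity beta_hat = beta * rho is exact for).
regressor_pair <- function(rewards, alpha_g, alpha_f,
                           type = c("value", "pe")) {
  type <- match.arg(type)
  col <- if (type == "value") "value" else "prediction_error"
  x_g <- build_regressors(simulate_learner(rewards, alpha_g))[[col]]
  x_f <- build_regressors(simulate_learner(rewards, alpha_f))[[col]]
  list(x_g = x_g, x_f = x_f, rho = cor(x_g, x_f))
}
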