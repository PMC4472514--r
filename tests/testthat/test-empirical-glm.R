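test_that("signal generation obeys its contract", {
  x <- matrix(withr::with_seed(1, rnorm(200)), ncol = 2)
  colnames(x) <- c("a", "b")
  y0 <- generate_signal(x, c(2, -1), sigma_fmri = 0, seed = 5)
  expect_equal(y0, as.numeric(x %*% c(2, -1)))

  y_noise <- generate_signal(x, c(0, 0), sigma_fmri = 1.3, seed = 6)
  expect_lt(abs(sd(y_noise) - 1.3), 4 * 1.3 / sqrt(2 * 100))

  expect_identical(generate_signal(x, c(1, 1), 1, seed = 7),
                   generate_signal(x, c(1, 1), 1, seed = 7))
  expect_error(generate_signal(x, c(1, 2, 3), 1, seed = 1), "match")
})

test_that("fit_ols solves the normal equations", {
  x <- withr::with_seed(2, rnorm(80))
  z <- withr::with_seed(3, rnorm(80))
  design <- with_intercept(x = x, z = z)

  # signal equal to one column: coefficient 1, zero residual
  fit <- fit_ols(x, design)
  expect_equal(unname(fit$coefficients), c(0, 1, 0), tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-8)
  expect_equal(fit$dof, 77)

  # residual orthogonality to every design column
  y <- withr::with_seed(4, 2 * x - z + rnorm(80))
  fit2 <- fit_ols(y, design)
  expect_lt(max(abs(crossprod(design, fit2$residuals))) / 80, 1e-10)
  expect_equal(unname(fit2$t_stats),
               unname(fit2$coefficients / fit2$standard_errors))

  # agreement with lm as an independent reference
  ref <- lm(y ~ x + z)
  expect_equal(unname(fit2$coefficients), unname(coef(ref)),
               tolerance = 1e-10)
  expect_equal(unname(fit2$standard_errors),
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-10)

  # rank deficiency is reported with the collinear column named
  expect_error(fit_ols(y, with_intercept(x = x, x2 = 2 * x)),
               "collinear.*x2")
})

test_that("fitting against a misspecified regressor attenuates by rho", {
  spec <- fixed_reward_spec(0.5, family = "bernoulli")
  r <- sample_rewards(spec, 150, seed = 41)
  pair <- regressor_pair(r, 0.15, 0.7, type = "value")
  oracle <- ols_replicate_oracle(pair$x_g, pair$x_f, beta = 2, sigma = 2,
                                 n_rep = 300, seed = 42)
  expect_lt(abs(oracle$mean_beta - 2 * pair$rho), 3 * oracle$se_beta)
})

test_that("log-likelihood profiles peak at the generating learning rate", {
  spec <- drifting_reward_spec(0.9836, 2.8, 4, baseline = 50)
  r <- sample_rewards(spec, 300, seed = 71)
  centred <- r$reward - 50
  x_g <- build_regressors(simulate_learner(centred, 0.36))$value
  y <- generate_signal(matrix(x_g), 1, 1 / 11, seed = 72)  # CNR = 11
  prof <- loglik_profile(y, centred, seq(0.01, 1, 0.01), which = "value")
  expect_s3_class(prof, "loglik_profile")
  expect_equal(max(prof$delta_loglik, na.rm = TRUE), 0)
  expect_lt(abs(attr(prof, "alpha_hat") - 0.36), 0.06)
  expect_true(all(prof$valid))
  expect_equal(nrow(prof), 100)
})

test_that("profiles flatten as the signal weakens", {
  spec <- fixed_reward_spec(0.5, family = "bernoulli")
  profile_range <- function(cnr, s) {
    r <- sample_rewards(spec, 120, seed = 80 + s)
    x_g <- build_regressors(simulate_learner(r, 0.4))$prediction_error
    y <- generate_signal(matrix(x_g), cnr, 1, seed = 180 + s)
    prof <- loglik_profile(y, r, seq(0.05, 1, 0.05), which = "pe")
    -min(prof$delta_loglik, na.rm = TRUE)
  }
  weak <- vapply(1:6, profile_range, numeric(1), cnr = 0.4)
  strong <- vapply(1:6, profile_range, numeric(1), cnr = 4)
  expect_lt(median(weak), median(strong))
  expect_lt(median(weak), 0.05 * median(strong))
})

test_that("degenerate grid points are flagged, not dropped", {
  # constant rewards with v_init at the fixed point: value regressor is
  # degenerate at every alpha, prediction errors identically zero
  r <- c(rep(1, 30), rep(0, 30))
  y <- withr::with_seed(91, rnorm(60))
  prof <- loglik_profile(y, r, c(0.2, 1), which = "value")
  expect_true(all(prof$valid))
  const <- rep(0.5, 60)
  expect_error(
    loglik_profile(y, const, c(0.5), which = "value", v_init = 0.5),
    "degenerate"
  )
})

test_that("group t test and envelope behave as random-effects analyses", {
  expect_error(group_ttest(rep(1, 16)), "zero variance")
  expect_error(group_ttest(3), "2 subjects")
  sym <- c(-2, -1, 1, 2)
  expect_equal(group_ttest(sym)$group_t, 0)
  g <- group_ttest(c(0.5, 0.8, 0.4, 0.9, 0.6))
  expect_equal(g$dof, 4L)
  expect_equal(g$group_t, unname(t.test(c(0.5, 0.8, 0.4, 0.9, 0.6))$statistic))

  # rejection rate across cohorts matches the noncentral-t power oracle
  n_subj <- 16
  mu <- 0.4
  sd_b <- 0.5
  crit <- qt(0.975, n_subj - 1)
  power <- 1 - pt(crit, n_subj - 1, ncp = mu * sqrt(n_subj) / sd_b) +
    pt(-crit, n_subj - 1, ncp = mu * sqrt(n_subj) / sd_b)
  n_cohort <- 400
  hits <- withr::with_seed(101, {
    sum(vapply(seq_len(n_cohort), function(i) {
      group_ttest(rnorm(n_subj, mu, sd_b))$p_value < 0.05
    }, logical(1)))
  })
  se <- sqrt(power * (1 - power) / n_cohort)
  expect_lt(abs(hits / n_cohort - power), 3 * se)
})

test_that("the best/worst envelope brackets the group curve", {
  curves <- withr::with_seed(111, matrix(rnorm(8 * 10, 1, 0.5), nrow = 8))
  env <- best_worst_envelope(curves)
  expect_equal(env$case, c("best", "worst"))
  # the selected per-subject values bracket every fixed-column mean
  col_means <- colMeans(curves)
  expect_true(all(env$mean_selected[1] >= col_means))
  expect_true(all(env$mean_selected[2] <= col_means))
  # and on this cohort the t statistics bracket the per-column group t
  col_ts <- apply(curves, 2, function(b) group_ttest(b)$group_t)
  expect_true(all(env$group_t[1] >= col_ts))
  expect_true(all(env$group_t[2] <= col_ts))

  # single grid point: best == worst == the plain group statistic
  one <- matrix(c(1, 2, 3, 2.5), ncol = 1)
  env1 <- best_worst_envelope(one)
  expect_equal(env1$group_t[1], env1$group_t[2])
  expect_equal(env1$group_t[1], group_ttest(one[, 1])$group_t)
  expect_error(best_worst_envelope(matrix(numeric(0), nrow = 0)), "subjects")
})

test_that("envelope width shrinks as the signal weakens", {
  # per-subject coefficient curves over an alpha grid at two CNRs
  alphas <- seq(0.1, 1, 0.1)
  spec <- fixed_reward_spec(0.5, family = "bernoulli")
  width <- function(cnr) {
    curves <- t(vapply(1:8, function(subj) {
      r <- sample_rewards(spec, 100, seed = 300 + subj)
      x_g <- build_regressors(simulate_learner(r, 0.3))$prediction_error
      y <- generate_signal(matrix(x_g), cnr, 1, seed = 400 + subj)
      vapply(alphas, function(a) {
        x_f <- build_regressors(simulate_learner(r, a))$prediction_error
        fit_ols(y, with_intercept(x = x_f))$coefficients[["x"]]
      }, numeric(1))
    }, numeric(length(alphas))))
    env <- best_worst_envelope(curves)
    env$mean_selected[1] - env$mean_selected[2]
  }
  expect_gt(width(1), width(0.1))
})

test_that("parameter recovery sharpens as trials are added", {
  # synthetic analogue of re-running the drifting-reward analysis with a
  # truncated session: shorter runs give flatter profiles and larger
  # recovery error
  spec <- drifting_reward_spec(0.9836, 2.8, 4, baseline = 50)
  recover <- function(n_trials, seed) {
    r <- sample_rewards(spec, n_trials, seed = seed)
    centred <- r$reward - 50
    x_g <- build_regressors(simulate_learner(centred, 0.36))$value
    y <- generate_signal(matrix(x_g), 1, 1 / 11, seed = seed + 1000)
    prof <- loglik_profile(y, centred, seq(0.02, 1, 0.02), which = "value")
    c(err = abs(attr(prof, "alpha_hat") - 0.36),
      range = -min(prof$delta_loglik, na.rm = TRUE))
  }
  short <- vapply(1:8, function(s) recover(40, 2000 + 7 * s), numeric(2))
  long <- vapply(1:8, function(s) recover(300, 2000 + 7 * s), numeric(2))
  expect_lte(mean(long["err", ]), mean(short["err", ]))
  expect_gt(mean(long["range", ]), mean(short["range", ]))
})
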