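#' Monte-Carlo validation of the closed-form correlations
#'
#' Draws random learning-rate pairs and reward regimes, simulates a pair
#' of Rescorla-Wagner learners on a shared long reward stream, and
#' compares the empirical Pearson correlation of their value and
#' prediction-error traces with the analytic closed forms. This is the
#' package's ground-truth check: the closed forms were accepted only
#' because they survive it.
#'
#' Each draw uses learning rates sampled uniformly on `[0.05, 1]` (small
#' rates need disproportionately long runs for the large-`T`
#' approximation), a regime chosen at random, and for drifting regimes a
#' decay uniform on `[0, 0.99]` and drift-to-noise ratio uniform on
#' `[0.1, 4.5]`. The first `burn_in` trials are discarded so
#' initial-condition transients (which the theory drops) do not bias the
#' comparison.
#'
#' @param n_pairs Number of random draws.
#' @param n_trials Trials per simulated stream (after burn-in).
#' @param seed Integer seed.
#' @param burn_in Trials discarded from the start of each stream.
#' @return A tibble with one row per draw and per regressor type:
#'   `draw`, `regime`, `alpha_g`, `alpha_f`, `gamma`,
#'   `drift_noise_ratio`, `type`, `rho_analytic`, `rho_empirical`,
#'   `abs_error`.
#' @examples
#' \donttest{
#' mc_validate(n_pairs = 3, n_trials = 20000, seed = 1)
#' }
#' @export
mc_validate <- function(n_pairs = 20, n_trials = 1e5, seed = 1,
                        burn_in = 1000) {
  stopifnot(n_pairs >= 1, n_trials >= 10, burn_in >= 0)
  draws <- with_seed(seed, tibble(
    draw = seq_len(n_pairs),
    alpha_g = stats::runif(n_pairs, 0.05, 1),
    alpha_f = stats::runif(n_pairs, 0.05, 1),
    regime = sample(c("fixed", "drifting"), n_pairs, replace = TRUE),
    gamma = stats::runif(n_pairs, 0, 0.99),
    drift_noise_ratio = stats::runif(n_pairs, 0.1, 4.5),
    m = stats::runif(n_pairs, -1, 1),
    sigma_n = stats::runif(n_pairs, 0.2, 2)
  ))
  draws$gamma[draws$regime == "fixed"] <- NA_real_
  draws$drift_noise_ratio[draws$regime == "fixed"] <- NA_real_
  res <- purrr::pmap(draws, function(draw, alpha_g, alpha_f, regime, gamma,
                                     drift_noise_ratio, m, sigma_n) {
    spec <- if (regime == "fixed") {
      fixed_reward_spec(m = m, sigma_n = sigma_n)
    } else {
      drifting_reward_spec(gamma = gamma,
                           sigma_d = drift_noise_ratio * sigma_n,
                           sigma_n = sigma_n, baseline = 0)
    }
    r <- sample_rewards(spec, n_trials + burn_in, seed = seed + 13L * draw)
    keep <- seq(burn_in + 1, n_trials + burn_in)
    tr_g <- simulate_learner(r, alpha_g)
    tr_f <- simulate_learner(r, alpha_f)
    emp_v <- cor(tr_g$value[keep], tr_f$value[keep])
    emp_pe <- cor(tr_g$prediction_error[keep], tr_f$prediction_error[keep])
    if (regime == "fixed") {
      ana_v <- value_corr_fixed(alpha_g, alpha_f)
      ana_pe <- pe_corr_fixed(alpha_g, alpha_f)
    } else {
      ana_v <- value_corr_drifting(alpha_g, alpha_f, gamma, drift_noise_ratio)
      ana_pe <- pe_corr_drifting(alpha_g, alpha_f, gamma, drift_noise_ratio)
    }
    tibble(
      draw = draw, regime = regime,
      alpha_g = alpha_g, alpha_f = alpha_f,
      gamma = gamma, drift_noise_ratio = drift_noise_ratio,
      type = c("value", "prediction_error"),
      rho_analytic = c(ana_v, ana_pe),
      rho_empirical = c(emp_v, emp_pe),
      abs_error = abs(c(ana_v - emp_v, ana_pe - emp_pe))
    )
  })
  dplyr::bind_rows(res)
}
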