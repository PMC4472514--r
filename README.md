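# rwsens

**How much does model-based regression care about the learning rate?**

Model-based fMRI regresses a neural signal on trial-by-trial latent
variables of a learning model — typically the value $V_t$ and reward
prediction error $\delta_t = r_t - V_t$ of a Rescorla–Wagner learner,
$V_{t+1} = V_t + \alpha\delta_t$. The analysis requires committing to a
learning rate $\alpha$, which is rarely known. `rwsens` is a toolkit for
asking, analytically and by simulation, what happens when the fitted
learning rate $\alpha_f$ differs from the generative one $\alpha_g$ — for
the people who run such analyses and the people who design the
experiments behind them.

The core results it implements:

* **Misspecified-regressor calculus.** With unit-variance regressors, the
  expected OLS coefficient is $\hat\beta = \beta\rho$, and the expected
  $t$ statistic is
  $\hat t = \rho\,\mathrm{CNR}\sqrt{T-2}\big/\sqrt{1+\mathrm{CNR}^2(1-\rho^2)}$,
  where $\rho = \rho(x_g, x_f)$ and $\mathrm{CNR} = \beta/\sigma$ is the
  contrast-to-noise ratio. Everything reduces to regressor correlations.
* **Closed-form correlations across learning rates.** For i.i.d. rewards,
  $$\rho(V_g,V_f) = \frac{\sqrt{\alpha_g\alpha_f(2-\alpha_g)(2-\alpha_f)}}
    {\alpha_g+\alpha_f-\alpha_g\alpha_f},\qquad
  \rho(\delta_g,\delta_f) = \frac{(\alpha_g+\alpha_f)
    \sqrt{(2-\alpha_g)(2-\alpha_f)}}{2(\alpha_g+\alpha_f-\alpha_g\alpha_f)},$$
  with the striking consequence $\rho(\delta_g,\delta_f) \ge 1/\sqrt2$:
  prediction-error regressors are substantially correlated no matter how
  wrong the learning rate is. For rewards drifting as a mean-reverting
  (Ornstein–Uhlenbeck) random walk, analogous closed forms depend only on
  the decay $\gamma$ and drift-to-noise ratio $\sigma_d/\sigma_n$.
* **Sensitivity maps and design tools.** Correlation and $t$-statistic
  surfaces over learning-rate pairs, an insensitivity metric (fraction of
  the surface with $\rho > 0.7$), scans of the $(\gamma,
  \sigma_d/\sigma_n)$ design space, and diagonal slices showing how
  sensitivity grows with CNR and trial count.
* **Empirical counterparts.** Synthetic-signal generation, OLS fitting,
  Gaussian log-likelihood profiles over candidate learning rates
  (parameter recovery), random-effects group tests and best/worst-case
  envelopes — plus a Monte-Carlo validator that checks every closed form
  against simulated learners.

All user-facing functions take and return plain tables (tibbles), chain
with the pipe, and have `tidy()`/`glance()`/`autoplot()` methods where a
fitted object or grid is involved.

## Worked example

```r
library(rwsens)

# Worst plausible mismatch for a prediction-error regressor, fixed rewards:
pe_corr_fixed(0.1, 0.9)
#> [1] 0.7943314

# Full sensitivity map on the dense grid, and its t-statistic image
grid <- corr_grid("fixed")
grid
#> <corr_grid> fixed regime, 1000 x 1000 learning rates in [0.001, 1]
#>   rho_value in [0.0447, 1.0000]; rho_pe in [0.7076, 1.0000]
t_grid(grid, cnr = 1, n_trials = 50)
#> <t_grid> fixed regime, CNR=1, T=50, two-tailed p < 0.001
#>   t_value in [0.219, 6.928] (81.4% significant); t_pe in [4.004, 6.928] (100.0% significant)
insensitivity_metric(grid$rho_pe)
#> [1] 1
```

Read: over *all* learning-rate pairs, the prediction-error correlation
never drops below 0.708, so at a typical CNR of 1 with 50 trials every
cell of the map clears $p < 0.001$ (worst-case $t = 4.0$) — a
prediction-error signal will be found even with a badly wrong learning
rate, and for the same reason the data cannot identify the learning rate.
The value surface, whose correlations reach down to 0.045, is the
sensitive one in this regime.

Recovery flips when the signal is strong. In the drifting-reward regime
($\gamma = 0.9836$, $\sigma_d/\sigma_n = 0.7$) at CNR 11 with 300 trials:

```r
spec <- drifting_reward_spec()
drift_noise_ratio(spec)
#> [1] 0.7
rewards <- sample_rewards(spec, 300, seed = 7)
centred <- rewards$reward - 50
x_g <- build_regressors(simulate_learner(centred, 0.36))$value
signal <- generate_signal(matrix(x_g), beta = 1, sigma_fmri = 1 / 11, seed = 8)
prof <- loglik_profile(signal, centred, seq(0.01, 1, 0.01), which = "value")
attr(prof, "alpha_hat")
#> [1] 0.36
```

The log-likelihood profile is sharply peaked and recovers the generating
learning rate exactly; `autoplot(prof)` draws it.

There is also a thin command-line wrapper (`inst/cli/rwsens`) over the
same functions, with subcommands `simulate-rewards`, `simulate-learner`,
`corr-map`, `t-map`, `design-scan`, `diagonal-slice`, `loglik-profile`,
`mc-validate` and `fixtures`, all writing CSV/JSON with a parameter log.

See the vignette (`vignettes/learning-rate-sensitivity.Rmd`) for the full
model account, conventions, and numerical choices.

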