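#' Simulate a Rescorla-Wagner learner on a reward sequence
#'
#' Runs the delta-rule update
#' \deqn{V_{t+1} = V_t + \alpha \delta_t, \qquad \delta_t = r_t - V_t}
#' over a sequence of rewards, producing the per-trial values and
#' prediction errors that serve as model-based regressors. The learning
#' rate \eqn{\alpha} is the fraction of each prediction error incorporated
#' into the value estimate; the analysis requires \eqn{0 < \alpha \le 1}.
#'
#' Trials are 1-based: `values[1] == v_init` and the value on trial
#' `t + 1` is determined by the reward on trial `t`. The recurrence is
#' evaluated exactly (it is a first-order linear filter), so the trace is
#' deterministic given its inputs.
#'
#' @param rewards Numeric vector of rewards, or a tibble with a `reward`
#'   column (e.g. from [sample_rewards()]).
#' @param alpha Learning rate in `(0, 1]`.
#' @param v_init Initial value `V_1` (reward units); default 0.
#' @return A `learner_trace`: a tibble with columns `trial`, `reward`,
#'   `value`, `prediction_error`, and attributes `alpha`, `v_init`.
#' @examples
#' tr <- simulate_learner(c(1, 0, 1), alpha = 0.5)
#' tr$value             # 0 0.50 0.25
#' tr$prediction_error  # 1 -0.50 0.75
#' @export
simulate_learner <- function(rewards, alpha, v_init = 0) {
  r <- as_reward_vector(rewards)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    abort("`alpha` must be a single number in (0, 1]: the theory holds for non-zero learning rates only.")
  }
  stopifnot(is.numeric(v_init), length(v_init) == 1L, is.finite(v_init))
  n <- length(r)
  v <- numeric(n)
  v[1] <- v_init
  if (n > 1) {
    # V_{t+1} = (1 - alpha) V_t + alpha r_t: recursive linear filter with
    # the initial condition folded into the first input term.
    v[-1] <- as.numeric(stats::filter(
      alpha * r[-n] + (1 - alpha) * c(v_init, rep(0, n - 2)),
      1 - alpha, method = "recursive"
    ))
  }
  out <- tibble(
    trial = seq_len(n),
    reward = r,
    value = v,
    prediction_error = r - v
  )
  structure(out, alpha = alpha, v_init = v_init,
            class = c("learner_trace", class(out)))
}

#' @export
print.learner_trace <- function(x, ...) {
  cat(sprintf("# A learner_trace: alpha = %g, v_init = %g\n",
              attr(x, "alpha"), attr(x, "v_init")))
  NextMethod()
}

#' Extract (optionally normalized) regressors from a learner trace
#'
#' Returns the value and prediction-error series of a trace as regressor
#' columns. With `normalize = TRUE` (the default, matching common
#' practice of mean-centring model-based regressors and scaling them to
#' unit standard deviation) each column is centred and divided by its
#' population SD (divisor `T`, the convention \eqn{\sigma(x) =
#' \sqrt{x^\top x / T}} used throughout the regression theory).
#'
#' @param trace A `learner_trace` from [simulate_learner()].
#' @param normalize Centre and scale each regressor to mean 0, SD 1
#'   (population convention)? Default `TRUE`.
#' @return A tibble with columns `trial`, `value`, `prediction_error`.
#' @examples
#' tr <- simulate_learner(c(1, 0, 1, 1, 0), alpha = 0.3)
#' build_regressors(tr)
#' @export
build_regressors <- function(trace, normalize = TRUE) {
  stopifnot(inherits(trace, "learner_trace"))
  v <- trace$value
  pe <- trace$prediction_error
  if (normalize) {
    v <- normalize_regressor(v, "value")
    pe <- normalize_regressor(pe, "prediction_error")
  }
  tibble(trial = trace$trial, value = v, prediction_error = pe)
}

# Population-SD (divisor T) standardisation; errors on degenerate input.
normalize_regressor <- function(x, label) {
  n <- length(x)
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / n)
  if (sigma == 0) {
    abort(sprintf(
      "Cannot normalize the `%s` regressor: it has zero variance.", label
    ))
  }
  (x - mu) / sigma
}
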