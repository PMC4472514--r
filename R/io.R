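#' Read and write the package's tabular formats
#'
#' All tabular artifacts are plain CSV with a header row. Readers
#' validate the header against the expected schema and insist that every
#' schema column parses as numeric (logical for significance masks),
#' reporting the offending column and the first offending row otherwise.
#' Writers emit numbers at full round-trip precision, so write-then-read
#' reproduces the values bit-faithfully.
#'
#' Schemas:
#' * rewards: `trial,reward` (+ optional `latent_mean`)
#' * learner trace: `trial,value,prediction_error`
#' * correlation/t grid (long): `alpha_g,alpha_f,rho_value,rho_pe`
#'   (+ optional `t_value,t_pe,sig_value,sig_pe`)
#' * log-likelihood profile: `alpha,delta_loglik`
#' * design scan: `gamma,drift_noise_ratio,metric_value,metric_pe`
#'
#' @param path File path.
#' @param x Table to write.
#' @name rwsens-io
NULL

read_table_schema <- function(path, required, optional = character(),
                              logical_cols = character()) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("File %s is missing required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  keep <- intersect(c(required, optional), names(df))
  df <- df[keep]
  for (col in keep) {
    if (col %in% logical_cols) {
      parsed <- as.logical(df[[col]])
    } else {
      parsed <- suppressWarnings(as.numeric(df[[col]]))
    }
    bad <- which(is.na(parsed) & !is.na(df[[col]]))
    if (length(bad) > 0 || anyNA(df[[col]])) {
      row <- if (length(bad) > 0) bad[1] else which(is.na(df[[col]]))[1]
      abort(sprintf("Column `%s` of %s has a non-numeric value at row %d.",
                    col, path, row))
    }
    df[[col]] <- parsed
  }
  as_tibble(df)
}

#' @rdname rwsens-io
#' @export
read_rewards <- function(path) {
  read_table_schema(path, c("trial", "reward"), optional = "latent_mean")
}

#' @rdname rwsens-io
#' @export
write_rewards <- function(x, path) {
  stopifnot(all(c("trial", "reward") %in% names(x)))
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname rwsens-io
#' @export
read_trace <- function(path) {
  read_table_schema(path, c("trial", "value", "prediction_error"))
}

#' @rdname rwsens-io
#' @param trace A `learner_trace` or a regressor tibble from
#'   [build_regressors()].
#' @export
write_trace <- function(trace, path) {
  stopifnot(all(c("trial", "value", "prediction_error") %in% names(trace)))
  readr::write_csv(
    as_tibble(trace)[c("trial", "value", "prediction_error")], path
  )
  invisible(path)
}

#' @rdname rwsens-io
#' @export
read_grid <- function(path) {
  read_table_schema(
    path, c("alpha_g", "alpha_f", "rho_value", "rho_pe"),
    optional = c("t_value", "t_pe", "sig_value", "sig_pe"),
    logical_cols = c("sig_value", "sig_pe")
  )
}

#' @rdname rwsens-io
#' @param grid A `corr_grid`, a `t_grid`, or an already-tidied long
#'   tibble.
#' @export
write_grid <- function(grid, path) {
  df <- if (inherits(grid, "corr_grid")) {
    tidy(grid)
  } else if (inherits(grid, "t_grid")) {
    tidy(grid)
  } else {
    as_tibble(grid)
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname rwsens-io
#' @param profile A `loglik_profile`.
#' @export
write_profile <- function(profile, path) {
  stopifnot(all(c("alpha", "delta_loglik") %in% names(profile)))
  readr::write_csv(as_tibble(profile)[c("alpha", "delta_loglik")], path)
  invisible(path)
}

#' @rdname rwsens-io
#' @export
read_profile <- function(path) {
  read_table_schema(path, c("alpha", "delta_loglik"))
}

#' Run configurations
#'
#' A run configuration bundles a scenario name, a reward-process
#' specification, learner and regression settings, grid specifications
#' and seeds into one serialisable object. Configurations round-trip
#' through YAML (15 significant digits) or JSON (full precision) by file
#' extension.
#'
#' @param scenario Scenario name.
#' @param reward Either a [fixed_reward_spec()] or a
#'   [drifting_reward_spec()].
#' @param learner List of learner settings (e.g. `alpha`, `v_init`).
#' @param regression List of regression settings (e.g. `cnr`,
#'   `n_trials`).
#' @param grids List of grid settings (e.g. `alpha_step`).
#' @param seed Integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(scenario, reward, learner = list(),
                       regression = list(), grids = list(), seed = 1L) {
  stopifnot(is.character(scenario), inherits(reward, "reward_spec"))
  structure(
    list(
      scenario = scenario,
      reward = c(
        list(kind = if (inherits(reward, "fixed_reward_spec")) "fixed"
             else "drifting"),
        unclass(reward)[!vapply(unclass(reward), is.function, logical(1))]
      ),
      learner = learner, regression = regression, grids = grids,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path Destination; `.json`, `.yaml` or `.yml`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(x, path, precision = 15L)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  reward <- x$reward
  spec <- if (identical(reward$kind, "fixed")) {
    fixed_reward_spec(m = reward$m, sigma_n = reward$sigma_n,
                      family = reward$family)
  } else {
    drifting_reward_spec(gamma = reward$gamma, sigma_d = reward$sigma_d,
                         sigma_n = reward$sigma_n, baseline = reward$baseline,
                         m_init = reward$m_init)
  }
  run_config(scenario = x$scenario, reward = spec,
             learner = x$learner %||% list(),
             regression = x$regression %||% list(),
             grids = x$grids %||% list(),
             seed = x$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
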