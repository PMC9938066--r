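# High-level commands behind the CLI: simulate / fit / train / rollout.
# Each is deterministic given the configuration (timestamps appear only
# in the log header).

open_run_log <- function(outdir, command) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(outdir, "run.log")
  writeLines(sprintf("# npodrl %s | started %s", command,
                     format(Sys.time(), "%Y-%m-%d %H:%M:%S")), path)
  path
}

log_line <- function(log_path, level, msg) {
  cat(sprintf("%s %s\n", level, msg), file = log_path, append = TRUE)
}

#' Simulate a synthetic population
#'
#' Generates the population described by the configuration's `simulate`
#' section and writes `dataset.csv`, `truth.csv` and the echoed spec.
#'
#' @param config A `run_config` (see [read_run_config()]).
#' @param outdir Output directory (defaults to the config's
#'   `output_dir`).
#' @return Named character vector of written paths, invisibly.
#' @export
run_simulate <- function(config, outdir = config$output_dir) {
  log <- open_run_log(outdir, "simulate")
  spec <- config_population_spec(config)
  pop <- generate_population(spec)
  paths <- write_population(pop, outdir)
  log_line(log, "INFO", sprintf("wrote %d subjects to %s",
                                length(pop$subjects), paths[["dataset"]]))
  invisible(paths)
}

resolve_fit_inputs <- function(config) {
  if (is.null(config$dataset))
    stop("config must set 'dataset' for this command")
  subjects <- read_pk_dataset(config$dataset)
  model_kind <- config$fit$model_kind
  if (is.null(model_kind)) model_kind <- config$environment$model_start
  bounds <- if (!is.null(config$fit$bounds))
    do.call(param_bounds, config$fit$bounds)
  else do.call(param_bounds,
               config$environment$initial_bounds[[as.character(model_kind)]])
  list(subjects = subjects, model_kind = as.integer(model_kind),
       bounds = bounds)
}

#' Fit the nonparametric model once
#'
#' Runs a single [npod_fit()] on the configured dataset, model and bounds
#' and writes `support.csv` (points + weights) with a `fit.json` sidecar.
#'
#' @inheritParams run_simulate
#' @return The `npml_result`, invisibly.
#' @export
run_fit <- function(config, outdir = config$output_dir) {
  log <- open_run_log(outdir, "fit")
  inp <- resolve_fit_inputs(config)
  fit <- npod_fit(inp$subjects, inp$bounds, inp$model_kind,
                  em = config_error_model(config),
                  control = config_npod_control(config))
  write_npml_result(fit, file.path(outdir, "support.csv"),
                    file.path(outdir, "fit.json"))
  log_line(log, "INFO", sprintf(
    "fit: %d support points, loglik %.6f, %d cycles, converged=%s",
    nrow(fit$grid), fit$loglik, fit$cycles, fit$converged))
  invisible(fit)
}

#' Train the SARSA agent
#'
#' Builds the model-search environment on the configured dataset and
#' trains the tabular agent, writing `qtable.json`, `episodes.csv` and
#' `steps.csv`.
#'
#' @inheritParams run_simulate
#' @return The [sarsa_train()] result, invisibly.
#' @export
run_train <- function(config, outdir = config$output_dir) {
  log <- open_run_log(outdir, "train")
  inp <- resolve_fit_inputs(config)
  env <- pk_environment(inp$subjects, config_env(config),
                        estimator = config_estimator(config))
  ac <- agent_config(alpha = config$agent$alpha, gamma = config$agent$gamma,
                     episodes = config$agent$episodes,
                     seed = config$agent$seed)
  res <- sarsa_train(env, ac)
  save_q_table(res$q, file.path(outdir, "qtable.json"))
  utils::write.csv(res$episodes, file.path(outdir, "episodes.csv"),
                   row.names = FALSE)
  utils::write.csv(res$steps, file.path(outdir, "steps.csv"),
                   row.names = FALSE)
  n_abort <- sum(res$episodes$aborted)
  if (n_abort > 0)
    log_line(log, "WARN", sprintf("%d/%d episodes aborted", n_abort,
                                  nrow(res$episodes)))
  log_line(log, "INFO", sprintf(
    "trained %d episodes, %d estimator calls, best episode reward %.6f",
    nrow(res$episodes), env$n_estimator_calls,
    max(res$episodes$total_reward)))
  invisible(res)
}

#' Evaluate a trained agent greedily
#'
#' Replays one greedy (epsilon = 0) episode with the given Q table and
#' writes `rollout-steps.csv` plus a `rollout.json` report with the final
#' log-likelihood, the structural model chosen, the support count and the
#' abort flag.
#'
#' @inheritParams run_simulate
#' @param qtable_path Path to a `qtable.json` ([save_q_table()]); `NULL`
#'   evaluates the untrained first-index policy.
#' @return The [greedy_rollout()] result, invisibly.
#' @export
run_rollout <- function(config, qtable_path = NULL,
                        outdir = config$output_dir) {
  log <- open_run_log(outdir, "rollout")
  inp <- resolve_fit_inputs(config)
  env <- pk_environment(inp$subjects, config_env(config),
                        estimator = config_estimator(config))
  q <- if (is.null(qtable_path)) q_table() else load_q_table(qtable_path)
  roll <- greedy_rollout(env, q)
  utils::write.csv(roll$steps, file.path(outdir, "rollout-steps.csv"),
                   row.names = FALSE)
  final_state <- roll$steps$state_key[nrow(roll$steps)]
  report <- list(
    total_reward = roll$total_reward, final_loglik = roll$final_loglik,
    model_chosen = as.integer(substr(env_final_model(env), 1, 1)),
    n_support = roll$n_support, aborted = roll$aborted,
    length = roll$length)
  jsonlite::write_json(report, file.path(outdir, "rollout.json"),
                       auto_unbox = TRUE, digits = NA)
  if (roll$aborted) log_line(log, "WARN", "rollout aborted")
  log_line(log, "INFO", sprintf("rollout reward %.6f in %d steps",
                                roll$total_reward, roll$length))
  invisible(roll)
}

env_final_model <- function(env) {
  as.character(env$state$active_model)
}
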