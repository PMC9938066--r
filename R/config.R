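# Run configuration: a versioned YAML schema aggregating every tunable
# constant (bounds, error polynomial, estimator tolerances, RL
# hyperparameters) so that runs are reproducible from one file.

default_run_config <- function() {
  list(
    version = 1L,
    output_dir = "runs",
    dataset = NULL,
    model = list(error = list(c0 = 0.1, c1 = 0.1, c2 = 0, c3 = 0)),
    estimator = list(backend = "npod", n_sobol = 51L, tol = 1e-4,
                     max_cycles = 100L, weight_floor = 1e-6,
                     merge_tol = 1e-4, nm_maxeval = 200L),
    fit = list(model_kind = NULL, bounds = NULL),
    environment = list(
      model_start = 2L, horizon = 30L, abort_penalty = -20000,
      initial_bounds = list(
        "1" = list(ke = c(0.001, 2), v = c(125, 625)),
        "2" = list(ke = c(0.001, 2), v = c(125, 625),
                   kcp = c(0.001, 10), kpc = c(10, 100)))),
    agent = list(alpha = 0.9, gamma = 1, episodes = 1000L, seed = 1L),
    simulate = list(
      n_subjects = 20L, model_kind = 1L, seed = 42L,
      outlier_fraction = 0.05,
      doses = list(list(start_time = 0, amount = 600, duration = 1)),
      obs_times = c(1, 2, 4, 6, 8, 12, 24),
      conc_floor = 0,
      parameters = list(
        ke = list(means = c(0.25, 0.7), sds = c(0.05, 0.05),
                  fractions = c(0.5, 0.5), range = c(0, 1)),
        v = list(means = 120, sds = 25, fractions = 1,
                 range = c(50, 200))),
      outlier_parameters = list(
        ke = list(means = 0.95, sds = 0.02, fractions = 1,
                  range = c(0, 1)))))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else
      base[[nm]] <- override[[nm]]
  }
  base
}

#' Read and validate a run configuration
#'
#' Reads a YAML configuration file and merges it over the package
#' defaults (which carry the standard model-search constants: alpha 0.9,
#' gamma 1, 1000 episodes, 30-step horizon, -20000 abort penalty, 51
#' Sobol points and the misplaced two-compartment starting bounds). A
#' shipped example lives at
#' `system.file("extdata", "example-config.yaml", package = "npodrl")`.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  validate_run_config(cfg)
}

#' Validate a run configuration list
#'
#' @param cfg A configuration list shaped like the YAML schema.
#' @return `cfg` with class `run_config`; errors describe the offending
#'   field.
#' @export
validate_run_config <- function(cfg) {
  ag <- cfg$agent
  if (ag$alpha < 0 || ag$alpha > 1) stop("agent.alpha must be in [0, 1]")
  if (ag$gamma < 0 || ag$gamma > 1) stop("agent.gamma must be in [0, 1]")
  if (ag$episodes < 1) stop("agent.episodes must be >= 1")
  if (cfg$environment$horizon < 1) stop("environment.horizon must be >= 1")
  if (!cfg$environment$model_start %in% c(1, 2))
    stop("environment.model_start must be 1 or 2")
  if (cfg$estimator$n_sobol < 1) stop("estimator.n_sobol must be >= 1")
  if (!cfg$estimator$backend %in% c("npod", "mock"))
    stop("estimator.backend must be 'npod' or 'mock'")
  sm <- cfg$simulate
  if (sm$n_subjects < 1) stop("simulate.n_subjects must be >= 1")
  if (sm$outlier_fraction < 0 || sm$outlier_fraction >= 0.5)
    stop("simulate.outlier_fraction must be in [0, 0.5)")
  # bounds must construct (checks 0 < lower < upper)
  for (mk in c("1", "2"))
    do.call(param_bounds, cfg$environment$initial_bounds[[mk]])
  structure(cfg, class = c("run_config", "list"))
}

config_error_model <- function(cfg) {
  do.call(error_model, cfg$model$error)
}

config_npod_control <- function(cfg) {
  es <- cfg$estimator
  npod_control(n_sobol = es$n_sobol, tol = es$tol,
               max_cycles = es$max_cycles, weight_floor = es$weight_floor,
               merge_tol = es$merge_tol, nm_maxeval = es$nm_maxeval)
}

config_env <- function(cfg) {
  env_config(
    initial_bounds = list(
      "1" = do.call(param_bounds, cfg$environment$initial_bounds[["1"]]),
      "2" = do.call(param_bounds, cfg$environment$initial_bounds[["2"]])),
    model_start = cfg$environment$model_start,
    horizon = cfg$environment$horizon,
    abort_penalty = cfg$environment$abort_penalty)
}

config_population_spec <- function(cfg) {
  sm <- cfg$simulate
  mix <- function(x) mixture_spec(
    means = as.numeric(x$means), sds = as.numeric(x$sds),
    fractions = if (is.null(x$fractions))
      rep(1 / length(x$means), length(x$means)) else as.numeric(x$fractions),
    range = as.numeric(x$range))
  population_spec(
    n_subjects = sm$n_subjects, model_kind = sm$model_kind,
    parameters = lapply(sm$parameters, mix),
    outlier_fraction = sm$outlier_fraction,
    outlier_parameters = lapply(sm$outlier_parameters, mix),
    doses = lapply(sm$doses, function(d)
      dose_event(d$start_time, d$amount, d$duration)),
    obs_times = as.numeric(sm$obs_times),
    em = config_error_model(cfg), conc_floor = sm$conc_floor,
    seed = sm$seed)
}

config_estimator <- function(cfg) {
  if (cfg$estimator$backend == "mock") mock_estimator()
  else npod_estimator(config_error_model(cfg), config_npod_control(cfg))
}
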