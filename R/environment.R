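# The model-search Markov decision process: discrete actions widen or
# narrow one bound of one parameter (x1.1 / x10/11) or switch the
# structural model; each step runs the nonparametric estimator on the
# resulting search space and rewards the change in log-likelihood.

invalid_bounds <- function(message) {
  stop(errorCondition(message, class = c("invalid_bounds", "npodrl_error")))
}

#' Environment configuration
#'
#' Initial search spaces per structural model, episode horizon and abort
#' penalty. The defaults start from a deliberately misplaced
#' two-compartment search space (`ke` in `[0.001, 2]`, `v` in
#' `[125, 625]`, `kcp` in `[0.001, 10]`, `kpc` in `[10, 100]`), a horizon
#' of 30 actions per episode and an abort penalty of -20000.
#'
#' @param initial_bounds Named list with elements `"1"` and `"2"`:
#'   [param_bounds()] for the one- and two-compartment models.
#' @param model_start Structural model active after reset (1 or 2).
#' @param horizon Maximum number of actions per episode.
#' @param abort_penalty Reward delivered when the estimator fails or an
#'   action produces an empty search space; the episode then terminates.
#' @return A list of class `env_config`.
#' @export
env_config <- function(
    initial_bounds = list(
      "1" = param_bounds(ke = c(0.001, 2), v = c(125, 625)),
      "2" = param_bounds(ke = c(0.001, 2), v = c(125, 625),
                         kcp = c(0.001, 10), kpc = c(10, 100))),
    model_start = 2L, horizon = 30L, abort_penalty = -20000) {
  stopifnot(all(c("1", "2") %in% names(initial_bounds)),
            identical(names(initial_bounds[["1"]]), c("ke", "v")),
            identical(names(initial_bounds[["2"]]),
                      c("ke", "v", "kcp", "kpc")),
            model_start %in% c(1L, 2L), horizon >= 1)
  structure(list(initial_bounds = initial_bounds,
                 model_start = as.integer(model_start),
                 horizon = as.integer(horizon),
                 abort_penalty = abort_penalty), class = "env_config")
}

count_names <- function(model_kind) {
  p <- model_param_names(model_kind)
  c(paste0("lower.", p), paste0("upper.", p))
}

initial_env_state <- function(config) {
  counts <- list("1" = stats::setNames(integer(4), count_names(1L)),
                 "2" = stats::setNames(integer(8), count_names(2L)))
  list(active_model = config$model_start, counts = counts,
       prev_loglik = NA_real_, steps_taken = 0L)
}

#' Canonical state key
#'
#' Encodes a search-space state as
#' `"<model>:{<lower offsets>,<upper offsets>}"`, listing the signed
#' integer step counts of every lower bound of the active model followed
#' by every upper bound (e.g. the untouched two-compartment start is
#' `"2:{0,0,0,0,0,0,0,0}"`). Step counts, not bound values, are encoded,
#' so opposite actions cancel exactly and equal states always share a
#' key.
#'
#' @param state An environment state as produced by the environment.
#' @return A single character key.
#' @export
encode_state <- function(state) {
  cnt <- state$counts[[as.character(state$active_model)]]
  sprintf("%d:{%s}", state$active_model, paste(cnt, collapse = ","))
}

#' Construct a bound or model-switch action
#'
#' @param kind One of `"increase_lower"`, `"increase_upper"`,
#'   `"decrease_lower"`, `"decrease_upper"`, `"switch_model"`.
#' @param param Target parameter name; `NA` for `switch_model`.
#' @return A list of class `pk_action` with a canonical `label`.
#' @export
pk_action <- function(kind, param = NA_character_) {
  kinds <- c("increase_lower", "increase_upper", "decrease_lower",
             "decrease_upper", "switch_model")
  stopifnot(kind %in% kinds)
  label <- if (kind == "switch_model") "switch_model"
  else sprintf("%s(%s)", kind, param)
  structure(list(kind = kind, param = param, label = label),
            class = "pk_action")
}

#' Enumerate available actions
#'
#' Actions in their canonical order for the active model: increase
#' lower/upper of each parameter pair, then the matching decreases, then
#' the model switch — 9 actions for the one-compartment model (two
#' parameters) and 17 for the two-compartment model (four parameters),
#' i.e. four actions per parameter plus one switch.
#'
#' @param state An environment state.
#' @return Ordered list of [pk_action()] objects.
#' @export
enumerate_actions <- function(state) {
  build <- function(params) {
    out <- list()
    for (grp in split(params, ceiling(seq_along(params) / 2))) {
      for (p in grp) {
        out <- c(out, list(pk_action("increase_lower", p),
                           pk_action("increase_upper", p)))
      }
      for (p in grp) {
        out <- c(out, list(pk_action("decrease_lower", p),
                           pk_action("decrease_upper", p)))
      }
    }
    out
  }
  params <- model_param_names(state$active_model)
  c(build(params), list(pk_action("switch_model")))
}

action_labels <- function(actions) {
  vapply(actions, `[[`, "", "label")
}

find_action <- function(state, label) {
  acts <- enumerate_actions(state)
  hit <- which(action_labels(acts) == label)
  if (!length(hit)) stop("action '", label, "' is not available here")
  acts[[hit]]
}

#' Bounds implied by a state
#'
#' Each signed step count scales its initial bound by `1.1^count`
#' (one increase step = x1.1, one decrease step = x10/11).
#'
#' @param state An environment state.
#' @param config The [env_config()].
#' @param model_kind Model whose bounds to derive (default: active).
#' @return A [param_bounds()] object; signals an `invalid_bounds`
#'   condition if any lower bound meets or exceeds its upper bound.
#' @export
derive_bounds <- function(state, config, model_kind = state$active_model) {
  b0 <- config$initial_bounds[[as.character(model_kind)]]
  cnt <- state$counts[[as.character(model_kind)]]
  out <- list()
  for (p in names(b0)) {
    lo <- b0[[p]][1] * 1.1^cnt[[paste0("lower.", p)]]
    up <- b0[[p]][2] * 1.1^cnt[[paste0("upper.", p)]]
    if (lo >= up)
      invalid_bounds(sprintf("empty search space for '%s' (%g >= %g)",
                             p, lo, up))
    out[[p]] <- c(lo, up)
  }
  do.call(param_bounds, out)
}

#' Apply an action to a state
#'
#' Bound actions adjust the targeted step count by +1 (increase, x1.1)
#' or -1 (decrease, x10/11); the model switch toggles the active model
#' and leaves both models' step counts intact, so an increase followed by
#' the matching decrease restores the original state key exactly.
#'
#' @param state An environment state.
#' @param action A [pk_action()] or its label.
#' @param config The [env_config()]; used to check that the resulting
#'   search space is non-empty (signals `invalid_bounds` otherwise).
#' @return The new state (step counter untouched; the environment
#'   advances it).
#' @export
apply_action <- function(state, action, config) {
  if (is.character(action)) action <- find_action(state, action)
  stopifnot(inherits(action, "pk_action"))
  ns <- state
  if (action$kind == "switch_model") {
    ns$active_model <- if (state$active_model == 1L) 2L else 1L
  } else {
    mk <- as.character(state$active_model)
    side <- if (grepl("lower", action$kind)) "lower" else "upper"
    delta <- if (grepl("increase", action$kind)) 1L else -1L
    key <- paste0(side, ".", action$param)
    if (!key %in% names(ns$counts[[mk]]))
      stop("parameter '", action$param, "' not in the active model")
    ns$counts[[mk]][[key]] <- ns$counts[[mk]][[key]] + delta
  }
  derive_bounds(ns, config)  # signals invalid_bounds on empty space
  ns
}

#' Estimator backend wrapping the nonparametric fit
#'
#' @param em [error_model()] used by the fit.
#' @param control [npod_control()] settings.
#' @return A function `(subjects, bounds, model_kind)` returning
#'   `list(loglik, n_support, cycles, converged)`; estimator failures
#'   propagate as `estimator_failure` conditions.
#' @export
npod_estimator <- function(em = error_model(), control = npod_control()) {
  force(em); force(control)
  function(subjects, bounds, model_kind) {
    fit <- npod_fit(subjects, bounds, model_kind, em = em, control = control)
    list(loglik = fit$loglik, n_support = nrow(fit$grid),
         cycles = fit$cycles, converged = fit$converged)
  }
}

#' Closed-form mock estimator backend
#'
#' A millisecond drop-in for the nonparametric fit, used to exercise the
#' environment and the learning loop. Returns a pseudo log-likelihood
#' that is highest when the active model equals `target_model` and the
#' log-bounds coincide with `target_bounds`, so bound-moving actions have
#' a learnable effect. An optional predicate forces estimator failures.
#'
#' @param target_model Structural model at which the pseudo likelihood
#'   peaks.
#' @param target_bounds Named list `"1"`/`"2"` of [param_bounds()] giving
#'   the peak location per model; defaults to the true one-compartment
#'   population ranges (`ke` in `[0.125, 1]`, `v` in `[50, 200]`) and the
#'   default two-compartment start.
#' @param base Pseudo log-likelihood at the peak.
#' @param model_penalty Penalty applied when the active model differs
#'   from `target_model`.
#' @param fail_if Optional `function(bounds, model_kind)`; a `TRUE`
#'   result raises an `estimator_failure`.
#' @return An estimator function with the same contract as
#'   [npod_estimator()].
#' @export
mock_estimator <- function(
    target_model = 1L,
    target_bounds = list(
      "1" = param_bounds(ke = c(0.125, 1), v = c(50, 200)),
      "2" = param_bounds(ke = c(0.125, 1), v = c(50, 200),
                         kcp = c(0.001, 10), kpc = c(10, 100))),
    base = -100, model_penalty = 50, fail_if = NULL) {
  force(target_model); force(target_bounds); force(base)
  force(model_penalty); force(fail_if)
  function(subjects, bounds, model_kind) {
    if (!is.null(fail_if) && isTRUE(fail_if(bounds, model_kind)))
      estimator_failure("mock estimator forced failure")
    tb <- bounds_matrix(target_bounds[[as.character(model_kind)]])
    bm <- bounds_matrix(bounds)
    dist <- sum((log(bm) - log(tb))^2)
    ll <- base - dist - if (model_kind == target_model) 0 else model_penalty
    list(loglik = ll, n_support = 1L, cycles = 0L, converged = TRUE)
  }
}

#' Model-search environment over a PK dataset
#'
#' Builds the reinforcement-learning environment: states are the active
#' structural model plus integer bound offsets, actions come from
#' [enumerate_actions()], and each step runs the estimator backend on the
#' updated search space. The reward of the first step of an episode is
#' the attained log-likelihood; later rewards are the change in
#' log-likelihood. An estimator failure or an empty search space yields
#' the abort penalty and terminates the episode, as does reaching the
#' horizon.
#'
#' @param subjects List of [subject_record()] objects.
#' @param config [env_config()].
#' @param estimator Estimator backend ([npod_estimator()] by default, or
#'   [mock_estimator()] for fast experiments).
#' @param em [error_model()] for the default backend.
#' @param control [npod_control()] for the default backend.
#' @return An object of class `pk_env` supporting [env_reset()] and
#'   [env_step()].
#' @export
pk_environment <- function(subjects, config = env_config(),
                           estimator = NULL, em = error_model(),
                           control = npod_control()) {
  if (is.null(estimator)) estimator <- npod_estimator(em, control)
  e <- new.env(parent = emptyenv())
  e$subjects <- prepare_subjects(subjects)
  e$config <- config
  e$estimator <- estimator
  e$state <- initial_env_state(config)
  e$terminated <- TRUE   # require reset before stepping
  e$n_estimator_calls <- 0L
  class(e) <- c("pk_env", "rl_env")
  e
}

#' Reset an environment to its initial state
#'
#' @param env An environment object.
#' @param ... Passed to methods.
#' @return List with the initial `state` key and the available `actions`
#'   (character labels).
#' @export
env_reset <- function(env, ...) UseMethod("env_reset")

#' Advance an environment by one action
#'
#' @param env An environment object.
#' @param action An action label (or [pk_action()]).
#' @param ... Passed to methods.
#' @return List with `state` (key), `reward`, `terminated`, `actions`
#'   (labels available in the new state; empty when terminated) and
#'   `info` (`loglik`, `n_support`, `aborted`, `estimator_cycles`).
#' @export
env_step <- function(env, action, ...) UseMethod("env_step")

#' Build an environment from closures
#'
#' Wraps a pair of functions into the environment contract used by
#' [sarsa_train()] and [greedy_rollout()]; handy for toy decision
#' processes and test doubles. `reset()` must return
#' `list(state, actions)` and `step(action)` must return
#' `list(state, reward, terminated, actions, info)`.
#'
#' @param reset Zero-argument reset closure.
#' @param step One-argument step closure taking an action label.
#' @return An object of class `fn_env` supporting [env_reset()] and
#'   [env_step()].
#' @export
rl_environment <- function(reset, step) {
  stopifnot(is.function(reset), is.function(step))
  structure(list(reset = reset, step = step),
            class = c("fn_env", "rl_env"))
}

#' @export
env_reset.fn_env <- function(env, ...) env$reset()

#' @export
env_step.fn_env <- function(env, action, ...) env$step(action)

#' @export
env_reset.pk_env <- function(env, ...) {
  env$state <- initial_env_state(env$config)
  env$terminated <- FALSE
  list(state = encode_state(env$state),
       actions = action_labels(enumerate_actions(env$state)))
}

#' @export
env_step.pk_env <- function(env, action, ...) {
  if (env$terminated)
    stop("episode is terminated; call env_reset() first")
  state <- env$state
  if (is.character(action)) action <- find_action(state, action)
  aborted <- FALSE
  ll <- NA_real_; n_support <- NA_integer_; cycles <- NA_integer_
  ns <- tryCatch(apply_action(state, action, env$config),
                 invalid_bounds = function(c) NULL)
  if (is.null(ns)) {
    # keep the attempted offsets for the state key, skip the estimator
    ns <- apply_action_counts_only(state, action)
    aborted <- TRUE
  } else {
    fit <- tryCatch({
      env$n_estimator_calls <- env$n_estimator_calls + 1L
      env$estimator(env$subjects, derive_bounds(ns, env$config),
                    ns$active_model)
    }, estimator_failure = function(c) NULL)
    if (is.null(fit)) {
      aborted <- TRUE
    } else {
      ll <- fit$loglik
      n_support <- fit$n_support
      cycles <- fit$cycles
    }
  }
  reward <- if (aborted) env$config$abort_penalty
  else if (is.na(state$prev_loglik)) ll
  else ll - state$prev_loglik
  if (!aborted) ns$prev_loglik <- ll
  ns$steps_taken <- state$steps_taken + 1L
  terminated <- aborted || ns$steps_taken >= env$config$horizon
  env$state <- ns
  env$terminated <- terminated
  list(state = encode_state(ns), reward = reward, terminated = terminated,
       actions = if (terminated) character(0) else
         action_labels(enumerate_actions(ns)),
       info = list(loglik = ll, n_support = n_support, aborted = aborted,
                   estimator_cycles = cycles))
}

# count/model update without the search-space validity check (used to
# form the terminal state key of an aborted transition)
apply_action_counts_only <- function(state, action) {
  ns <- state
  if (action$kind == "switch_model") {
    ns$active_model <- if (state$active_model == 1L) 2L else 1L
  } else {
    mk <- as.character(state$active_model)
    side <- if (grepl("lower", action$kind)) "lower" else "upper"
    delta <- if (grepl("increase", action$kind)) 1L else -1L
    key <- paste0(side, ".", action$param)
    ns$counts[[mk]][[key]] <- ns$counts[[mk]][[key]] + delta
  }
  ns
}

#' @export
print.pk_env <- function(x, ...) {
  cat(sprintf(
    "<model-search environment> %d subjects, horizon %d, model %d active\n",
    length(x$subjects), x$config$horizon, x$state$active_model))
  cat(sprintf("  state: %s   estimator calls: %d\n",
              encode_state(x$state), x$n_estimator_calls))
  invisible(x)
}
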