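# Tabular on-policy SARSA with an epsilon-greedy behaviour policy.
# Q(s, a) is stored in a hashed environment keyed by state key and action
# label; unseen pairs read as exactly 0.

#' Create an empty action-value table
#'
#' @return An object of class `q_table`. Lookups of never-updated
#'   state-action pairs return exactly 0.
#' @export
q_table <- function() {
  structure(list(store = new.env(parent = emptyenv(), hash = TRUE)),
            class = "q_table")
}

q_key <- function(state, action) paste(state, action, sep = " || ")

info_field <- function(res, name, default = NA) {
  v <- res$info[[name]]
  if (is.null(v)) default else v
}

#' Read an action value
#'
#' @param q A [q_table()].
#' @param state State key.
#' @param action Action label.
#' @return The stored value, or 0 if the pair was never updated.
#' @export
q_get <- function(q, state, action) {
  v <- q$store[[q_key(state, action)]]
  if (is.null(v)) 0 else v
}

#' Write an action value
#'
#' @param q A [q_table()].
#' @param state State key.
#' @param action Action label.
#' @param value New value.
#' @return `q`, invisibly.
#' @export
q_set <- function(q, state, action, value) {
  assign(q_key(state, action), value, envir = q$store)
  invisible(q)
}

#' @export
print.q_table <- function(x, ...) {
  cat(sprintf("<action-value table> %d stored state-action pairs\n",
              length(ls(x$store))))
  invisible(x)
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random action is taken;
#' otherwise the action with maximal Q value (ties broken uniformly at
#' random). Under this rule a unique greedy action is selected with
#' probability `1 - epsilon + epsilon/|A|` and every other action with
#' probability `epsilon/|A|`. Uses R's global random-number stream.
#'
#' @param q A [q_table()].
#' @param state State key.
#' @param actions Character vector of available action labels.
#' @param epsilon Exploration probability in `[0, 1]`.
#' @return One action label.
#' @export
select_action <- function(q, state, actions, epsilon) {
  stopifnot(length(actions) >= 1, epsilon >= 0, epsilon <= 1)
  if (epsilon > 0 && stats::runif(1) < epsilon)
    return(actions[[sample.int(length(actions), 1L)]])
  vals <- vapply(actions, function(a) q_get(q, state, a), 0)
  best <- which(vals == max(vals))
  if (length(best) > 1L) best <- best[[sample.int(length(best), 1L)]]
  actions[[best]]
}

#' One SARSA temporal-difference update
#'
#' Applies
#' `Q(s,a) <- Q(s,a) + alpha * (r + gamma * Q(s',a') - Q(s,a))`.
#' For a terminal next state the bootstrap term `Q(s',a')` is 0.
#'
#' @param q A [q_table()] (updated in place).
#' @param state,action Current state key and action label.
#' @param reward Observed reward.
#' @param next_state,next_action Successor pair; ignored when
#'   `terminal = TRUE`.
#' @param alpha Learning rate in `[0, 1]`.
#' @param gamma Discount factor in `[0, 1]`.
#' @param terminal Whether `next_state` is terminal.
#' @return The updated value of `(state, action)`.
#' @export
sarsa_update <- function(q, state, action, reward, next_state = NULL,
                         next_action = NULL, alpha = 0.9, gamma = 1,
                         terminal = FALSE) {
  stopifnot(alpha >= 0, alpha <= 1, gamma >= 0, gamma <= 1)
  boot <- if (terminal) 0 else q_get(q, next_state, next_action)
  old <- q_get(q, state, action)
  new <- old + alpha * (reward + gamma * boot - old)
  q_set(q, state, action, new)
  new
}

#' SARSA agent configuration
#'
#' @param alpha Learning rate (default 0.9).
#' @param gamma Discount factor (default 1).
#' @param episodes Number of training episodes (default 1000).
#' @param seed RNG seed for reproducible training.
#' @param epsilon Exploration schedule: a function mapping the 1-based
#'   episode index to epsilon. The default `1/episode` makes the first
#'   episode fully exploratory and decays thereafter.
#' @return A list of class `agent_config`.
#' @export
agent_config <- function(alpha = 0.9, gamma = 1, episodes = 1000L,
                         seed = 1L, epsilon = function(e) 1 / e) {
  stopifnot(alpha >= 0, alpha <= 1, gamma >= 0, gamma <= 1, episodes >= 1,
            is.function(epsilon))
  structure(list(alpha = alpha, gamma = gamma,
                 episodes = as.integer(episodes), seed = as.integer(seed),
                 epsilon = epsilon), class = "agent_config")
}

#' Train a SARSA agent on an environment
#'
#' Runs the on-policy control loop: for each episode, reset the
#' environment, pick an action epsilon-greedily, then repeatedly step,
#' pick the successor action, and update `Q(s,a)` from the quintuple
#' `(s, a, r, s', a')` until the episode terminates (horizon reached or
#' aborted; aborted transitions are updated with the abort reward and a
#' terminal bootstrap of 0). Fully reproducible given `config$seed`.
#'
#' @param env An environment supporting [env_reset()]/[env_step()].
#' @param config An [agent_config()].
#' @param q Optionally, a [q_table()] to continue training.
#' @return List with `q` (the trained table), `episodes` (one row per
#'   episode: `episode, total_reward, length, aborted, final_loglik`) and
#'   `steps` (one row per step:
#'   `episode, step, state_key, action, reward, loglik, n_support,
#'   aborted`).
#' @export
sarsa_train <- function(env, config = agent_config(), q = q_table()) {
  set.seed(config$seed)
  ep_rows <- vector("list", config$episodes)
  step_rows <- list()
  for (e in seq_len(config$episodes)) {
    eps <- config$epsilon(e)
    init <- env_reset(env)
    s <- init$state
    a <- select_action(q, s, init$actions, eps)
    total <- 0; nstep <- 0L; aborted <- FALSE; final_ll <- NA_real_
    repeat {
      res <- env_step(env, a)
      nstep <- nstep + 1L
      total <- total + res$reward
      ll <- info_field(res, "loglik", NA_real_)
      if (!is.na(ll)) final_ll <- ll
      aborted <- aborted || isTRUE(info_field(res, "aborted", FALSE))
      step_rows[[length(step_rows) + 1L]] <- data.frame(
        episode = e, step = nstep, state_key = s, action = a,
        reward = res$reward, loglik = ll,
        n_support = info_field(res, "n_support", NA_integer_),
        aborted = isTRUE(info_field(res, "aborted", FALSE)))
      if (res$terminated) {
        sarsa_update(q, s, a, res$reward, alpha = config$alpha,
                     gamma = config$gamma, terminal = TRUE)
        break
      }
      a2 <- select_action(q, res$state, res$actions, eps)
      sarsa_update(q, s, a, res$reward, res$state, a2,
                   alpha = config$alpha, gamma = config$gamma)
      s <- res$state
      a <- a2
    }
    ep_rows[[e]] <- data.frame(episode = e, total_reward = total,
                               length = nstep, aborted = aborted,
                               final_loglik = final_ll)
  }
  list(q = q, episodes = do.call(rbind, ep_rows),
       steps = do.call(rbind, step_rows))
}

#' Greedy evaluation rollout
#'
#' Plays one episode with `epsilon = 0`, breaking ties among maximal Q
#' values by the lowest action index, so the rollout is deterministic for
#' a fixed table. On an untrained table (all values 0) this selects the
#' first listed action at every step.
#'
#' @param env An environment supporting [env_reset()]/[env_step()].
#' @param q A [q_table()].
#' @return List with `steps` (per-step data frame), `total_reward`,
#'   `final_loglik`, `n_support`, `aborted` and `length`.
#' @export
greedy_rollout <- function(env, q) {
  init <- env_reset(env)
  s <- init$state
  actions <- init$actions
  rows <- list(); total <- 0; final_ll <- NA_real_
  n_support <- NA_integer_; aborted <- FALSE
  repeat {
    vals <- vapply(actions, function(a) q_get(q, s, a), 0)
    a <- actions[[which.max(vals)]]   # lowest index among ties
    res <- env_step(env, a)
    total <- total + res$reward
    ll <- info_field(res, "loglik", NA_real_)
    if (!is.na(ll)) {
      final_ll <- ll
      n_support <- info_field(res, "n_support", NA_integer_)
    }
    aborted <- aborted || isTRUE(info_field(res, "aborted", FALSE))
    rows[[length(rows) + 1L]] <- data.frame(
      step = length(rows) + 1L, state_key = s, action = a,
      reward = res$reward, loglik = ll,
      aborted = isTRUE(info_field(res, "aborted", FALSE)))
    if (res$terminated) break
    s <- res$state
    actions <- res$actions
  }
  steps <- do.call(rbind, rows)
  list(steps = steps, total_reward = total, final_loglik = final_ll,
       n_support = n_support, aborted = aborted, length = nrow(steps))
}

#' Serialize an action-value table to JSON
#'
#' Keys the JSON object by state key, then by action label.
#'
#' @param q A [q_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_q_table <- function(q, path) {
  keys <- sort(ls(q$store))
  nested <- list()
  for (k in keys) {
    parts <- strsplit(k, " || ", fixed = TRUE)[[1]]
    nested[[parts[1]]][[parts[2]]] <- q$store[[k]]
  }
  jsonlite::write_json(nested, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an action-value table from JSON
#'
#' @param path Path written by [save_q_table()].
#' @return A [q_table()].
#' @export
load_q_table <- function(path) {
  nested <- jsonlite::read_json(path)
  q <- q_table()
  for (s in names(nested))
    for (a in names(nested[[s]]))
      q_set(q, s, a, as.numeric(nested[[s]][[a]]))
  q
}
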