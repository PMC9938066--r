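# Independent oracles used across the suite: numerical ODE integration
# (deSolve) for the analytic kinetics, projected-gradient ascent for the
# simplex weight problem, and value iteration for toy decision processes.

# ---- ODE oracle -----------------------------------------------------------

ode_rhs_1c <- function(t, y, parms) {
  list(parms$rate(t) - parms$ke * y[1])
}

ode_rhs_2c <- function(t, y, parms) {
  dxc <- parms$rate(t) - (parms$ke + parms$kcp) * y[1] + parms$kpc * y[2]
  dxp <- parms$kcp * y[1] - parms$kpc * y[2]
  list(c(dxc, dxp))
}

# integrate the full dosing timeline numerically and return predicted
# concentrations at the subject's observation times
ode_profile <- function(subject, params) {
  t_obs <- vapply(subject$observations, `[[`, 0, "time")
  bol <- Filter(function(d) d$duration == 0, subject$doses)
  inf <- Filter(function(d) d$duration > 0, subject$doses)
  rate_fn <- function(t) {
    if (!length(inf)) return(0)
    sum(vapply(inf, function(d)
      if (t >= d$start_time && t < d$start_time + d$duration)
        d$amount / d$duration else 0, 0))
  }
  breaks <- sort(unique(c(0, vapply(bol, `[[`, 0, "start_time"),
                          unlist(lapply(inf, function(d)
                            c(d$start_time, d$start_time + d$duration))),
                          t_obs)))
  n_cmt <- if (inherits(params, "params_1c")) 1L else 2L
  rhs <- if (n_cmt == 1L) ode_rhs_1c else ode_rhs_2c
  parms <- c(unclass(params), list(rate = rate_fn))
  y <- rep(0, n_cmt)
  pred <- numeric(length(t_obs))
  for (j in seq_along(breaks)) {
    tj <- breaks[j]
    for (d in bol) if (d$start_time == tj) y[1] <- y[1] + d$amount
    hit <- which(t_obs == tj)
    if (length(hit)) pred[hit] <- y[1] / params$v
    if (j < length(breaks)) {
      mid_rate <- rate_fn((tj + breaks[j + 1]) / 2)
      parms$rate <- function(t) mid_rate
      out <- deSolve::lsoda(y, c(tj, breaks[j + 1]), rhs, parms,
                            rtol = 1e-11, atol = 1e-12)
      y <- as.numeric(out[nrow(out), -1])
    }
  }
  pred
}

# ---- simplex weight oracle ------------------------------------------------

project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

# maximize sum_i log( (S w)_i ) over the simplex by projected-gradient
# ascent with backtracking; independent of the package's EM/Frank-Wolfe
# path
simplex_oracle <- function(log_psi, iters = 20000) {
  row_max <- apply(log_psi, 1, max)
  s <- exp(log_psi - row_max)
  k <- ncol(s)
  f <- function(w) sum(log(as.vector(s %*% w)))
  w <- rep(1 / k, k)
  fw <- f(w)
  step <- 1
  for (i in seq_len(iters)) {
    g <- as.vector(t(s) %*% (1 / as.vector(s %*% w)))
    repeat {
      w2 <- project_simplex(w + step * g / max(abs(g)))
      f2 <- f(w2)
      if (is.finite(f2) && f2 >= fw - 1e-14) break
      step <- step / 2
      if (step < 1e-14) { w2 <- w; f2 <- fw; break }
    }
    if (abs(f2 - fw) < 1e-13 && i > 100) { w <- w2; fw <- f2; break }
    w <- w2; fw <- f2
  }
  list(weights = w, loglik = sum(row_max) + fw)
}

# ---- toy decision process + value-iteration oracle ------------------------

# deterministic 4-state chain: "right" advances toward s4 (reward 10,
# terminal), "left" retreats (stay at s1); every move costs 1
toy_chain_env <- function(horizon = 10L) {
  pos <- 1L; steps <- 0L
  actions <- c("left", "right")
  rl_environment(
    reset = function() {
      pos <<- 1L; steps <<- 0L
      list(state = paste0("s", pos), actions = actions)
    },
    step = function(action) {
      steps <<- steps + 1L
      pos <<- if (action == "right") pos + 1L else max(pos - 1L, 1L)
      done <- pos == 4L || steps >= horizon
      reward <- if (pos == 4L) 10 - 1 else -1
      list(state = paste0("s", pos), reward = reward, terminated = done,
           actions = if (done) character(0) else actions,
           info = list(loglik = NA_real_, n_support = NA_integer_,
                       aborted = FALSE, estimator_cycles = NA_integer_))
    })
}

# optimal action values for the toy chain by value iteration
toy_chain_optimal <- function(gamma = 1) {
  v <- c(0, 0, 0, 0)
  for (i in 1:200) {
    q_right <- c(-1 + gamma * v[2], -1 + gamma * v[3], 9, 0)
    q_left <- c(-1 + gamma * v[1], -1 + gamma * v[2], -1 + gamma * v[3], 0)
    v_new <- pmax(q_right, q_left)
    v_new[4] <- 0
    if (max(abs(v_new - v)) < 1e-12) break
    v <- v_new
  }
  list(v = v,
       q_right = c(-1 + gamma * v[2], -1 + gamma * v[3], 9),
       q_left = c(-1 + gamma * v[1], -1 + gamma * v[2], -1 + gamma * v[3]))
}

# ---- shared fixtures ------------------------------------------------------

random_params_1c <- function() {
  params_1c(ke = stats::runif(1, 0.02, 2), v = stats::runif(1, 20, 300))
}

random_params_2c <- function() {
  params_2c(ke = stats::runif(1, 0.02, 2), v = stats::runif(1, 20, 300),
            kcp = stats::runif(1, 0.01, 5), kpc = stats::runif(1, 0.01, 5))
}

random_regimen_subject <- function(id = "X") {
  doses <- list(dose_event(0, stats::runif(1, 100, 800),
                           sample(c(0, 0.5, 1, 2), 1)),
                dose_event(stats::runif(1, 4, 8), stats::runif(1, 100, 600),
                           sample(c(0, 1), 1)))
  subject_record(id, doses,
                 lapply(c(0.5, 1, 3, 6, 9, 12, 20), observation))
}

tiny_population <- function(n = 5, seed = 7) {
  generate_population(population_spec(
    n_subjects = n, seed = seed, outlier_fraction = 0))
}

cheap_control <- function() {
  npod_control(n_sobol = 8, max_cycles = 2, nm_maxeval = 30, tol = 0.1)
}
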