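make_mock_env <- function(config = env_config(), fail_if = NULL, n = 2) {
  pop <- tiny_population(n = n)
  pk_environment(pop$subjects, config,
                 estimator = mock_estimator(fail_if = fail_if))
}

test_that("action enumeration follows the canonical per-model lists", {
  cfg <- env_config(model_start = 1L)
  s1 <- npodrl:::initial_env_state(cfg)
  a1 <- enumerate_actions(s1)
  expect_length(a1, 9)
  expect_identical(
    npodrl:::action_labels(a1),
    c("increase_lower(ke)", "increase_upper(ke)", "increase_lower(v)",
      "increase_upper(v)", "decrease_lower(ke)", "decrease_upper(ke)",
      "decrease_lower(v)", "decrease_upper(v)", "switch_model"))

  s2 <- npodrl:::initial_env_state(env_config(model_start = 2L))
  a2 <- enumerate_actions(s2)
  expect_length(a2, 17)
  expect_identical(a2[[17]]$kind, "switch_model")
  expect_identical(
    npodrl:::action_labels(a2)[9:16],
    c("increase_lower(kcp)", "increase_upper(kcp)", "increase_lower(kpc)",
      "increase_upper(kpc)", "decrease_lower(kcp)", "decrease_upper(kcp)",
      "decrease_lower(kpc)", "decrease_upper(kpc)"))
})

test_that("bound actions scale by 1.1 and 10/11 and invert exactly", {
  cfg <- env_config()
  s <- npodrl:::initial_env_state(cfg)
  s2 <- apply_action(s, "increase_upper(ke)", cfg)
  expect_equal(derive_bounds(s2, cfg)$ke[2], 2 * 1.1)
  s3 <- apply_action(s2, "decrease_upper(ke)", cfg)
  expect_identical(encode_state(s3), encode_state(s))

  s4 <- apply_action(s, "decrease_lower(v)", cfg)
  expect_equal(derive_bounds(s4, cfg)$v[1], 125 * 10 / 11)

  # switching preserves both models' offsets
  s5 <- apply_action(s2, "switch_model", cfg)
  expect_equal(s5$active_model, 1L)
  expect_identical(encode_state(s5), "1:{0,0,0,0}")
  s6 <- apply_action(s5, "switch_model", cfg)
  expect_identical(encode_state(s6), encode_state(s2))
})

test_that("increase/decrease round-trips restore the key over random walks", {
  cfg <- env_config()
  set.seed(101)
  for (rep in 1:1000) {
    s <- npodrl:::initial_env_state(cfg)
    for (k in seq_len(sample(0:10, 1))) {
      lab <- sample(npodrl:::action_labels(enumerate_actions(s)), 1)
      s <- tryCatch(apply_action(s, lab, cfg), npodrl_error = function(c) s)
    }
    key <- encode_state(s)
    acts <- enumerate_actions(s)
    bound_acts <- Filter(function(a) a$kind != "switch_model", acts)
    a <- bound_acts[[sample(length(bound_acts), 1)]]
    inverse <- list(increase_lower = "decrease_lower",
                    increase_upper = "decrease_upper",
                    decrease_lower = "increase_lower",
                    decrease_upper = "increase_upper")[[a$kind]]
    s2 <- tryCatch({
      tmp <- apply_action(s, a, cfg)
      apply_action(tmp, pk_action(inverse, a$param), cfg)
    }, npodrl_error = function(c) NULL)
    if (!is.null(s2)) expect_identical(encode_state(s2), key)
  }
})

test_that("state keys encode the active model and integer offsets", {
  cfg <- env_config()
  s <- npodrl:::initial_env_state(cfg)
  expect_identical(encode_state(s), "2:{0,0,0,0,0,0,0,0}")
  s2 <- apply_action(s, "increase_upper(ke)", cfg)
  k1 <- strsplit(encode_state(s), "[,{}]")[[1]]
  k2 <- strsplit(encode_state(s2), "[,{}]")[[1]]
  expect_equal(sum(k1 != k2), 1)

  # replay determinism
  set.seed(55)
  for (i in 1:10) {
    labs <- character(0)
    s <- npodrl:::initial_env_state(cfg)
    for (k in 1:6) {
      lab <- sample(npodrl:::action_labels(enumerate_actions(s)), 1)
      s <- tryCatch(apply_action(s, lab, cfg), npodrl_error = function(c) s)
      labs <- c(labs, lab)
    }
    s_replay <- npodrl:::initial_env_state(cfg)
    for (lab in labs)
      s_replay <- tryCatch(apply_action(s_replay, lab, cfg),
                           npodrl_error = function(c) s_replay)
    expect_identical(encode_state(s_replay), encode_state(s))
  }
})

test_that("reset restores the configured start and clears history", {
  env <- make_mock_env()
  r1 <- env_reset(env)
  expect_identical(r1$state, "2:{0,0,0,0,0,0,0,0}")
  expect_length(r1$actions, 17)
  expect_equal(derive_bounds(env$state, env$config)$ke, c(0.001, 2))
  env_step(env, r1$actions[1])
  r2 <- env_reset(env)
  expect_identical(r2$state, r1$state)
  expect_true(is.na(env$state$prev_loglik))

  cfg <- env_config(model_start = 1L,
                    initial_bounds = list(
                      "1" = param_bounds(ke = c(0.01, 3), v = c(100, 500)),
                      "2" = param_bounds(ke = c(0.001, 2), v = c(125, 625),
                                         kcp = c(0.001, 10),
                                         kpc = c(10, 100))))
  env2 <- make_mock_env(cfg)
  r3 <- env_reset(env2)
  expect_identical(r3$state, "1:{0,0,0,0}")
  expect_equal(derive_bounds(env2$state, cfg)$ke, c(0.01, 3))
})

test_that("rewards are the log-likelihood then its increments", {
  env <- make_mock_env()
  r <- env_reset(env)
  res1 <- env_step(env, "increase_lower(ke)")
  expect_equal(res1$reward, res1$info$loglik)
  res2 <- env_step(env, "increase_lower(ke)")
  expect_equal(res2$reward, res2$info$loglik - res1$info$loglik)
  expect_false(res1$terminated)

  # telescoping over a full mock episode
  env_reset(env)
  total <- 0; last_ll <- NA
  repeat {
    res <- env_step(env, "increase_lower(ke)")
    total <- total + res$reward
    if (!is.na(res$info$loglik)) last_ll <- res$info$loglik
    if (res$terminated) break
  }
  expect_equal(total, last_ll, tolerance = 1e-10)
})

test_that("estimator failure aborts with the fixed penalty", {
  env <- make_mock_env(fail_if = function(bounds, model_kind)
    bounds$ke[1] > 0.00105)
  env_reset(env)
  res <- env_step(env, "increase_lower(ke)")
  expect_equal(res$reward, -20000)
  expect_true(res$terminated)
  expect_true(res$info$aborted)
  expect_error(env_step(env, "increase_lower(ke)"), "terminated")
})

test_that("episodes terminate at the horizon", {
  env <- make_mock_env(env_config(horizon = 5L))
  env_reset(env)
  n <- 0
  repeat {
    res <- env_step(env, "increase_upper(v)")
    n <- n + 1
    if (res$terminated) break
  }
  expect_equal(n, 5)
  expect_length(res$actions, 0)
})

test_that("an empty search space is folded into the abort path", {
  # shrink the feasible ratio so a few decreases of the upper bound
  # cross the lower bound
  cfg <- env_config(initial_bounds = list(
    "1" = param_bounds(ke = c(0.5, 0.7), v = c(100, 140)),
    "2" = param_bounds(ke = c(0.5, 0.7), v = c(100, 140),
                       kcp = c(1, 1.3), kpc = c(1, 1.3))),
    model_start = 1L)
  env <- make_mock_env(cfg)
  env_reset(env)
  res <- NULL
  for (i in 1:5) {
    res <- env_step(env, "decrease_upper(ke)")
    if (res$terminated) break
  }
  expect_true(res$info$aborted)
  expect_equal(res$reward, -20000)
  expect_true(res$terminated)
})
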