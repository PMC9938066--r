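test_that("unseen state-action pairs read as exactly zero", {
  q <- q_table()
  expect_identical(q_get(q, "s", "a"), 0)
  q_set(q, "s", "a", 2.5)
  expect_identical(q_get(q, "s", "a"), 2.5)
  expect_identical(q_get(q, "s", "b"), 0)
})

test_that("epsilon-greedy selection follows the stated probability law", {
  q <- q_table()
  acts <- c("a1", "a2", "a3", "a4")
  q_set(q, "s", "a3", 1)

  set.seed(1)
  picks <- replicate(200, select_action(q, "s", acts, epsilon = 0))
  expect_true(all(picks == "a3"))

  # epsilon = 1: uniform over all actions (chi-square within 3 sigma)
  set.seed(2)
  picks <- replicate(10000, select_action(q, "s", acts, epsilon = 1))
  counts <- table(factor(picks, levels = acts))
  chisq <- sum((counts - 2500)^2 / 2500)
  expect_lt(chisq, qchisq(1 - 2 * pnorm(-3), df = 3))

  # all-zero table: any epsilon behaves uniformly (ties broken at random)
  q0 <- q_table()
  set.seed(3)
  picks <- replicate(10000, select_action(q0, "s", acts, epsilon = 0))
  counts <- table(factor(picks, levels = acts))
  chisq <- sum((counts - 2500)^2 / 2500)
  expect_lt(chisq, qchisq(1 - 2 * pnorm(-3), df = 3))
})

test_that("the temporal-difference update applies the textbook rule", {
  q <- q_table()
  q_set(q, "s", "a", 3)
  sarsa_update(q, "s", "a", reward = 7, "s2", "a2", alpha = 0, gamma = 1)
  expect_equal(q_get(q, "s", "a"), 3)

  sarsa_update(q, "s", "a", reward = 7, "s2", "a2", alpha = 1, gamma = 0)
  expect_equal(q_get(q, "s", "a"), 7)

  q2 <- q_table()
  new <- sarsa_update(q2, "s", "a", reward = 5, "s2", "a2",
                      alpha = 0.9, gamma = 1)
  expect_equal(new, 4.5)

  # terminal transitions bootstrap from zero
  q3 <- q_table()
  q_set(q3, "s2", "a2", 100)
  sarsa_update(q3, "s", "a", reward = 1, "s2", "a2", alpha = 1, gamma = 1,
               terminal = TRUE)
  expect_equal(q_get(q3, "s", "a"), 1)
})

test_that("training is reproducible and leaves unvisited pairs at zero", {
  pop <- tiny_population(n = 2)
  cfg <- agent_config(episodes = 10L, seed = 99L)
  env1 <- pk_environment(pop$subjects, env_config(horizon = 6L),
                         estimator = mock_estimator())
  env2 <- pk_environment(pop$subjects, env_config(horizon = 6L),
                         estimator = mock_estimator())
  r1 <- sarsa_train(env1, cfg)
  r2 <- sarsa_train(env2, cfg)
  f1 <- tempfile(); f2 <- tempfile()
  save_q_table(r1$q, f1); save_q_table(r2$q, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(r1$episodes, r2$episodes)
  expect_identical(r1$steps, r2$steps)

  expect_identical(q_get(r1$q, "never-seen", "increase_lower(ke)"), 0)

  # round trip through JSON
  q_back <- load_q_table(f1)
  some <- r1$steps[1, ]
  expect_equal(q_get(q_back, some$state_key, some$action),
               q_get(r1$q, some$state_key, some$action))
})

test_that("one episode of horizon one performs exactly one update", {
  calls <- 0L
  env <- rl_environment(
    reset = function() list(state = "s", actions = c("a", "b")),
    step = function(action) {
      calls <<- calls + 1L
      list(state = "t", reward = 1, terminated = TRUE,
           actions = character(0), info = list())
    })
  res <- sarsa_train(env, agent_config(episodes = 1L, seed = 4L))
  expect_equal(calls, 1L)
  stored <- ls(res$q$store)
  expect_length(stored, 1)
})

test_that("SARSA learns the optimal policy of a deterministic toy chain", {
  env <- toy_chain_env()
  res <- sarsa_train(env, agent_config(alpha = 0.9, gamma = 1,
                                       episodes = 500L, seed = 7L))
  oracle <- toy_chain_optimal()
  for (i in 1:3) {
    s <- paste0("s", i)
    expect_gt(q_get(res$q, s, "right"), q_get(res$q, s, "left"))
    expect_equal(q_get(res$q, s, "right"), oracle$q_right[i],
                 tolerance = 0.05)
  }
  roll <- greedy_rollout(env, res$q)
  expect_equal(roll$total_reward, oracle$v[1])
  expect_equal(roll$length, 3)
})

test_that("greedy rollouts break ties by lowest action index", {
  env <- toy_chain_env()
  roll <- greedy_rollout(env, q_table())
  # empty table: the first-listed action ("left") is chosen every step
  expect_true(all(roll$steps$action == "left"))
  expect_lte(roll$length, 10)
})

test_that("mock-environment training improves episode rewards over time", {
  pop <- tiny_population(n = 2)
  env <- pk_environment(pop$subjects, env_config(horizon = 10L),
                        estimator = mock_estimator())
  res <- sarsa_train(env, agent_config(episodes = 120L, seed = 11L))
  ep <- res$episodes$total_reward
  n <- length(ep)
  first <- mean(ep[1:(n %/% 10)])
  last <- mean(ep[(n - n %/% 10 + 1):n])
  expect_gte(last, first)
})
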