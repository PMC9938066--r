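test_that("likelihood matrix matches direct density computation", {
  # a support point predicting one observation exactly with unit SD
  # contributes the standard-normal peak density
  s <- subject_record("a", list(dose_event(0, 100, 0)),
                      list(observation(0, 2)))
  em1 <- error_model(c0 = 1, c1 = 0)
  grid <- matrix(c(0.1, 50), 1, dimnames = list(NULL, c("ke", "v")))
  lp <- log_likelihood_matrix(list(s), grid, em1, 1L)
  expect_equal(lp[1, 1], log(1 / sqrt(2 * pi)), tolerance = 1e-12)

  # duplicated subject gives a duplicated row
  lp2 <- log_likelihood_matrix(list(s, s), grid, em1, 1L)
  expect_equal(lp2[1, ], lp2[2, ])

  # random small instance vs direct (non-log) product of densities
  set.seed(5)
  pop <- tiny_population(n = 3)
  g <- sobol_init(param_bounds(ke = c(0.05, 1), v = c(60, 180)), 4)
  em <- error_model()
  lp3 <- log_likelihood_matrix(pop$subjects, g, em, 1L)
  for (i in 1:3) for (k in 1:4) {
    p <- params_1c(g[k, "ke"], g[k, "v"])
    pred <- predict_profile(pop$subjects[[i]], p)
    y <- vapply(pop$subjects[[i]]$observations, `[[`, 0, "value")
    direct <- prod(stats::dnorm(y, pred, error_sd(em, pred)))
    expect_equal(lp3[i, k], log(direct), tolerance = 1e-10)
  }
})

test_that("weight optimization attains the simplex optimum", {
  # K = 1: all mass on the single point
  lp <- matrix(c(-1.5, -2.5), 2, 1)
  ws <- optimize_weights(lp)
  expect_equal(ws$weights, 1)
  expect_equal(ws$loglik, -4)

  # identity likelihood matrix: symmetry forces equal weights
  lp <- log(diag(2))
  ws <- optimize_weights(lp)
  expect_equal(ws$weights, c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(ws$loglik, 2 * log(0.5), tolerance = 1e-9)

  # random instances vs independent projected-gradient oracle
  set.seed(31)
  for (i in 1:8) {
    n <- sample(2:8, 1); k <- sample(2:8, 1)
    lp <- matrix(stats::rnorm(n * k, sd = 3), n, k)
    ws <- optimize_weights(lp)
    oracle <- simplex_oracle(lp)
    expect_equal(ws$loglik, oracle$loglik, tolerance = 1e-6)
    expect_lte(ws$kkt, 1 + 1e-6)
    expect_equal(sum(ws$weights), 1, tolerance = 1e-10)
    expect_true(all(ws$weights >= 0))
  }
})

test_that("weight optimization signals failure on an impossible row", {
  lp <- matrix(c(-1, -2, -Inf, -Inf), 2, 2, byrow = TRUE)
  expect_error(optimize_weights(lp), class = "estimator_failure")
})

test_that("condensation removes negligible points and merges duplicates", {
  b <- param_bounds(ke = c(0.01, 1), v = c(50, 200))
  g <- rbind(c(0.2, 100), c(0.2, 100), c(0.8, 150))
  colnames(g) <- c("ke", "v")

  out <- condense(g, c(0.3, 0.7, 0), b)
  expect_equal(nrow(out$grid), 1)
  expect_equal(out$weights, 1)
  expect_equal(unname(out$grid[1, ]), c(0.2, 100))

  out2 <- condense(g[c(1, 3), ], c(0.5, 0.5), b)
  expect_equal(nrow(out2$grid), 2)
  expect_equal(out2$weights, c(0.5, 0.5))

  out3 <- condense(g, c(1, 0, 0), b)
  expect_equal(nrow(out3$grid), 1)
  expect_equal(out3$weights, 1)
})

test_that("refinement moves a lone point to the subject's own optimum", {
  set.seed(9)
  pop <- tiny_population(n = 1)
  b <- param_bounds(ke = c(0.05, 1.5), v = c(60, 200))
  em <- error_model()
  start <- matrix(c(0.9, 180), 1, dimnames = list(NULL, c("ke", "v")))
  moved <- refine_points(start, 1, pop$subjects, b, em, 1L,
                         nm_maxeval = 400)
  # dense grid-search oracle for the individual ML estimate
  kk <- seq(0.05, 1.5, length.out = 120)
  vv <- seq(60, 200, length.out = 120)
  gg <- as.matrix(expand.grid(ke = kk, v = vv))
  lp <- log_likelihood_matrix(pop$subjects, gg, em, 1L)
  opt <- gg[which.max(lp[1, ]), ]
  final <- moved[nrow(moved), ]
  expect_equal(unname(final["ke"]), unname(opt["ke"]), tolerance = 0.05)
  expect_equal(unname(final["v"]), unname(opt["v"]), tolerance = 5)
})

test_that("refinement never decreases the post-solve log-likelihood", {
  set.seed(13)
  pop <- tiny_population(n = 4)
  b <- param_bounds(ke = c(0.05, 1.5), v = c(60, 200))
  em <- error_model()
  anchor <- sobol_init(b, 6)
  ws0 <- optimize_weights(log_likelihood_matrix(pop$subjects, anchor, em, 1L))
  cand <- refine_points(anchor, ws0$weights, pop$subjects, b, em, 1L)
  ws1 <- optimize_weights(log_likelihood_matrix(pop$subjects, cand, em, 1L))
  expect_gte(ws1$loglik, ws0$loglik - 1e-9)

  # an anchor already at a local optimum stays put (same objective:
  # a lone point refined twice with a generous budget)
  lone <- sobol_init(b, 1)
  opt1 <- refine_points(lone, 1, pop$subjects, b, em, 1L, nm_maxeval = 1000)
  opt1 <- opt1[nrow(opt1), , drop = FALSE]
  opt2 <- refine_points(opt1, 1, pop$subjects, b, em, 1L, nm_maxeval = 1000)
  u <- abs(opt2[nrow(opt2), ] - opt1[1, ])
  expect_lt(u[["ke"]] / 1.45, 0.02)
  expect_lt(u[["v"]] / 140, 0.02)
})

test_that("npod_fit satisfies its structural guarantees", {
  set.seed(17)
  pop <- tiny_population(n = 1)
  fit1 <- npod_fit(pop$subjects, param_bounds(ke = c(0.05, 1.5),
                                              v = c(60, 200)),
                   control = cheap_control())
  expect_lte(nrow(fit1$grid), 1)

  pop5 <- tiny_population(n = 5, seed = 3)
  fit5 <- npod_fit(pop5$subjects, param_bounds(ke = c(0.05, 1.5),
                                               v = c(60, 200)),
                   control = npod_control(n_sobol = 16, max_cycles = 10))
  expect_lte(nrow(fit5$grid), 5)
  expect_true(all(diff(fit5$loglik_trace) >= -1e-9))
  expect_equal(sum(fit5$weights), 1, tolerance = 1e-10)
  expect_true(all(fit5$weights >= 0))
  # reported loglik equals the mixture likelihood at the reported solution
  lp <- log_likelihood_matrix(pop5$subjects, fit5$grid, error_model(), 1L)
  mix <- sum(apply(lp + rep(log(fit5$weights), each = 5), 1, function(r) {
    m <- max(r); m + log(sum(exp(r - m)))
  }))
  expect_equal(fit5$loglik, mix, tolerance = 1e-8)
})

test_that("bounds excluding the population degrade or abort the fit", {
  set.seed(19)
  pop <- tiny_population(n = 4)
  good <- npod_fit(pop$subjects, param_bounds(ke = c(0.05, 1.5),
                                              v = c(60, 200)),
                   control = cheap_control())
  bad <- tryCatch(
    npod_fit(pop$subjects, param_bounds(ke = c(5, 50), v = c(60, 200)),
             control = cheap_control()),
    estimator_failure = function(c) NULL)
  if (is.null(bad)) {
    succeed()
  } else {
    expect_lt(bad$loglik, good$loglik - 100)
  }
})

test_that("fit serialization writes support points and metadata", {
  set.seed(29)
  pop <- tiny_population(n = 3)
  fit <- npod_fit(pop$subjects, param_bounds(ke = c(0.05, 1.5),
                                             v = c(60, 200)),
                  control = cheap_control())
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_npml_result(fit, csv, js)
  df <- read.csv(csv)
  expect_identical(names(df), c("ke", "v", "weight"))
  expect_equal(sum(df$weight), 1, tolerance = 1e-8)
  meta <- jsonlite::read_json(js)
  expect_equal(meta$loglik, fit$loglik, tolerance = 1e-12)
  expect_equal(meta$model_kind, 1L)
})
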