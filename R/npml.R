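# Nonparametric maximum-likelihood estimation of the mixing distribution
# in the NPOD style: a discrete set of weighted support points phi_k with
# weights w_k maximizing prod_i sum_k w_k p(Y_i | phi_k).

#' Signal an estimator failure
#'
#' Raised when the nonparametric estimator cannot produce a solution for
#' the current bounds/model (e.g. every candidate support point leaves
#' some subject's data essentially impossible, or the weight solve is
#' infeasible). The model-search environment converts this condition into
#' an episode abort.
#'
#' @param message Human-readable description.
#' @return Does not return; signals a condition of class
#'   `estimator_failure`.
#' @export
estimator_failure <- function(message) {
  stop(errorCondition(message, class = c("estimator_failure", "npodrl_error")))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# group subjects sharing a dose regimen and sampling schedule so one
# prediction serves the whole group (pure cache; results are identical
# to the per-subject path)
prepare_subjects <- function(subjects) {
  if (!is.null(attr(subjects, "npodrl_groups"))) return(subjects)
  sig <- vapply(subjects, function(s) {
    paste(c(vapply(s$doses, function(d)
      sprintf("%.15g/%.15g/%.15g", d$start_time, d$amount, d$duration), ""),
      sprintf("%.15g", obs_times(s))), collapse = "|")
  }, "")
  groups <- lapply(split(seq_along(subjects), sig), function(idx) {
    list(idx = idx, template = subjects[[idx[1]]],
         ymat = vapply(subjects[idx], obs_values,
                       numeric(length(obs_times(subjects[[idx[1]]])))))
  })
  attr(subjects, "npodrl_groups") <- unname(groups)
  subjects
}

# log p(Y_i | phi) for every subject, for a single support point
log_psi_column <- function(subjects, phi, em, model_kind) {
  params <- params_from_vector(phi, model_kind)
  groups <- attr(subjects, "npodrl_groups")
  if (is.null(groups)) {
    return(vapply(subjects, function(s) {
      pred <- predict_profile(s, params)
      sd <- error_sd(em, pred)
      if (any(sd <= 0)) return(-Inf)
      sum(stats::dnorm(obs_values(s), mean = pred, sd = sd, log = TRUE))
    }, 0))
  }
  out <- numeric(length(subjects))
  for (g in groups) {
    pred <- predict_profile(g$template, params)
    sd <- error_sd(em, pred)
    if (any(sd <= 0)) {
      out[g$idx] <- -Inf
    } else {
      ymat <- matrix(g$ymat, nrow = length(pred))
      out[g$idx] <- colSums(stats::dnorm(ymat, mean = pred, sd = sd,
                                         log = TRUE))
    }
  }
  out
}

#' Subject-by-support-point log-likelihood matrix
#'
#' Computes `log p(Y_i | phi_k)` for every subject `i` and support point
#' `phi_k`, assuming independent Normal observation errors with standard
#' deviation given by the assay error polynomial evaluated at the model
#' prediction. All arithmetic is in log space. A support point at which
#' the error polynomial yields a non-positive standard deviation is
#' flagged with `-Inf` for the affected subjects.
#'
#' @param subjects List of [subject_record()] objects.
#' @param grid Support-point matrix (rows = points, named parameter
#'   columns), e.g. from [sobol_init()].
#' @param em An [error_model()].
#' @param model_kind 1 (one-compartment) or 2 (two-compartment).
#' @return An N x K numeric matrix of log-likelihood contributions.
#' @export
log_likelihood_matrix <- function(subjects, grid, em, model_kind) {
  stopifnot(length(subjects) >= 1, nrow(grid) >= 1)
  out <- vapply(seq_len(nrow(grid)), function(k)
    log_psi_column(subjects, grid[k, ], em, model_kind),
    numeric(length(subjects)))
  matrix(out, nrow = length(subjects))
}

#' Maximum-likelihood weights on the probability simplex
#'
#' Given the log-likelihood matrix, finds nonnegative weights summing to
#' one that maximize `sum_i log sum_k w_k Psi_ik`. This is a concave
#' problem over the simplex; it is solved by multiplicative (EM)
#' fixed-point updates accelerated with Frank-Wolfe line searches, run to
#' the first-order optimality certificate
#' `max_k (1/N) sum_i Psi_ik / (Psi w)_i <= 1 + kkt_tol`.
#'
#' @param log_psi N x K matrix of `log p(Y_i | phi_k)`.
#' @param kkt_tol Optimality-certificate tolerance (default 1e-6).
#' @param max_iter Iteration cap.
#' @return List with `weights` (length K, sums to 1), `loglik` (value of
#'   the objective at the solution), `kkt` (the certificate value) and
#'   `iterations`.
#' @export
optimize_weights <- function(log_psi, kkt_tol = 1e-6, max_iter = 20000L) {
  n <- nrow(log_psi); k <- ncol(log_psi)
  row_max <- apply(log_psi, 1, max)
  if (any(!is.finite(row_max)))
    estimator_failure("a subject has no finite likelihood at any support point")
  s <- exp(log_psi - row_max)   # row-scaled Psi, entries in (0, 1]
  w <- rep(1 / k, k)
  kkt <- Inf; it <- 0L
  repeat {
    it <- it + 1L
    denom <- as.vector(s %*% w)
    if (any(denom <= 0))
      estimator_failure("weight optimization is infeasible (underflow)")
    g <- colMeans(s / denom)
    kkt <- max(g)
    if (kkt <= 1 + kkt_tol || it >= max_iter) break
    w <- w * g
    w <- pmax(w, 0); w <- w / sum(w)
    if (it %% 10L == 0L) {
      # Frank-Wolfe step toward the steepest vertex, exact line search
      j <- which.max(g)
      dfs <- function(t) sum((s[, j] - denom) / ((1 - t) * denom + t * s[, j]))
      if (dfs(0) > 0) {
        t_star <- if (dfs(1 - 1e-12) >= 0) 1 - 1e-12 else
          stats::uniroot(dfs, c(0, 1 - 1e-12), tol = 1e-12)$root
        w <- (1 - t_star) * w
        w[j] <- w[j] + t_star
        w <- w / sum(w)
      }
    }
  }
  list(weights = w, loglik = sum(row_max + log(as.vector(s %*% w))),
       kkt = kkt, iterations = it)
}

#' Condense a weighted support grid
#'
#' Removes support points carrying negligible weight and merges points
#' that coincide up to `merge_tol` in bounds-scaled coordinates (merged
#' location is the weight-averaged position). Weights are renormalized to
#' sum to one.
#'
#' @param grid Support-point matrix.
#' @param weights Weight vector aligned with `grid` rows.
#' @param bounds [param_bounds()] used to scale coordinates.
#' @param weight_floor Minimum retained weight (default 1e-6).
#' @param merge_tol Euclidean merge distance in the unit box
#'   (default 1e-4).
#' @return List with condensed `grid` and `weights`.
#' @export
condense <- function(grid, weights, bounds, weight_floor = 1e-6,
                     merge_tol = 1e-4) {
  keep <- weights > weight_floor
  if (!any(keep))
    estimator_failure("all support points fell below the weight floor")
  grid <- grid[keep, , drop = FALSE]
  weights <- weights[keep]
  u <- scale_to_unit(grid, bounds)
  ord <- order(weights, decreasing = TRUE)
  centers <- list(); cw <- c()
  for (idx in ord) {
    merged <- FALSE
    for (ci in seq_along(centers)) {
      if (sqrt(sum((u[idx, ] - centers[[ci]]$u)^2)) < merge_tol) {
        tot <- cw[ci] + weights[idx]
        centers[[ci]]$u <- (centers[[ci]]$u * cw[ci] +
                              u[idx, ] * weights[idx]) / tot
        centers[[ci]]$x <- (centers[[ci]]$x * cw[ci] +
                              grid[idx, ] * weights[idx]) / tot
        cw[ci] <- tot
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      centers[[length(centers) + 1L]] <- list(u = u[idx, ], x = grid[idx, ])
      cw <- c(cw, weights[idx])
    }
  }
  out <- do.call(rbind, lapply(centers, `[[`, "x"))
  colnames(out) <- colnames(grid)
  list(grid = out, weights = cw / sum(cw))
}

#' Refine support points by per-point local search
#'
#' The current grid is treated as an anchor set. Each support point in
#' turn is allowed to move, with all other anchor points and all weights
#' held fixed, by Nelder-Mead maximization of the mixture log-likelihood.
#' The search runs in a logistic transform of log-parameter space, which
#' is scale-invariant and keeps moved points strictly inside the bounds
#' without the flat clipping plateaus that trap a simplex search.
#' Returns the anchor set plus the moved points, with near-duplicates
#' removed.
#'
#' @param grid Anchor support-point matrix.
#' @param weights Anchor weights (aligned with `grid` rows).
#' @param subjects List of [subject_record()] objects.
#' @param bounds [param_bounds()].
#' @param em [error_model()].
#' @param model_kind 1 or 2.
#' @param nm_maxeval Nelder-Mead evaluation budget per point.
#' @param dedup_tol Bounds-scaled distance below which two candidate
#'   points are considered identical.
#' @return Candidate support-point matrix (anchor plus moved points).
#' @export
refine_points <- function(grid, weights, subjects, bounds, em, model_kind,
                          nm_maxeval = 200L, dedup_tol = 1e-4) {
  k <- nrow(grid)
  m <- log(bounds_matrix(bounds))
  span <- m["upper", ] - m["lower", ]
  to_theta <- function(phi) {
    u <- (log(phi) - m["lower", ]) / span
    stats::qlogis(pmin(pmax(u, 1e-6), 1 - 1e-6))
  }
  to_phi <- function(theta) exp(m["lower", ] + span * stats::plogis(theta))
  log_psi <- log_likelihood_matrix(subjects, grid, em, model_kind)
  lw <- log(weights)
  moved <- matrix(NA_real_, k, ncol(grid))
  for (j in seq_len(k)) {
    fixed <- if (k == 1L) rep(-Inf, length(subjects)) else
      apply(log_psi[, -j, drop = FALSE] +
              rep(lw[-j], each = length(subjects)), 1, logsumexp)
    obj <- function(theta) {
      col <- log_psi_column(subjects, to_phi(theta), em, model_kind)
      val <- sum(pmax(fixed, lw[j] + col) +
                   log1p(exp(-abs(fixed - (lw[j] + col)))))
      if (!is.finite(val)) -1e300 else val
    }
    res <- tryCatch(
      stats::optim(to_theta(grid[j, ]), obj, method = "Nelder-Mead",
                   control = list(fnscale = -1, maxit = nm_maxeval)),
      error = function(e) NULL)
    moved[j, ] <- if (is.null(res)) grid[j, ] else to_phi(res$par)
  }
  colnames(moved) <- colnames(grid)
  cand <- rbind(grid, moved)
  u <- scale_to_unit(cand, bounds)
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      later <- (i + 1L):nrow(cand)
      d <- sqrt(rowSums((u[later, , drop = FALSE] -
                           matrix(u[i, ], length(later), ncol(u),
                                  byrow = TRUE))^2))
      keep[later[d < dedup_tol]] <- FALSE
    }
  }
  cand[keep, , drop = FALSE]
}

#' Control settings for the nonparametric estimator
#'
#' @param n_sobol Number of Sobol initial support points (default 51).
#' @param tol Convergence tolerance on the log-likelihood improvement per
#'   cycle (default 1e-4).
#' @param max_cycles Maximum refine/weight/condense cycles (default 100).
#' @param weight_floor Condensation weight floor (default 1e-6).
#' @param merge_tol Condensation merge distance in bounds-scaled space
#'   (default 1e-4).
#' @param nm_maxeval Nelder-Mead budget per support point (default 200).
#' @param underflow Log-likelihood floor: a subject whose best
#'   `log p(Y_i | phi_k)` over the grid is below this value triggers an
#'   estimator failure (default -700).
#' @param kkt_tol Weight-solve optimality tolerance (default 1e-6).
#' @return A list of class `npod_control`.
#' @export
npod_control <- function(n_sobol = 51L, tol = 1e-4, max_cycles = 100L,
                         weight_floor = 1e-6, merge_tol = 1e-4,
                         nm_maxeval = 200L, underflow = -700,
                         kkt_tol = 1e-6) {
  structure(list(n_sobol = as.integer(n_sobol), tol = tol,
                 max_cycles = as.integer(max_cycles),
                 weight_floor = weight_floor, merge_tol = merge_tol,
                 nm_maxeval = as.integer(nm_maxeval), underflow = underflow,
                 kkt_tol = kkt_tol), class = "npod_control")
}

check_underflow <- function(log_psi, underflow) {
  worst <- min(apply(log_psi, 1, max))
  if (!is.finite(worst) || worst < underflow)
    estimator_failure(
      "search space contains no adequate support point for some subject")
}

#' Nonparametric maximum-likelihood fit (NPOD style)
#'
#' Estimates the mixing distribution of the population PK parameters as a
#' discrete set of weighted support points. The grid is initialized with
#' a Sobol sequence inside the bounds; each cycle then (i) refines every
#' support point by Nelder-Mead local search with the rest of the anchor
#' fixed, (ii) re-solves the simplex-constrained weight problem on the
#' anchor plus moved points, and (iii) condenses low-weight and duplicate
#' points. Cycling stops when the log-likelihood improves by less than
#' `control$tol` or `control$max_cycles` is reached. The post-solve
#' log-likelihood sequence is non-decreasing, and the final number of
#' support points never exceeds the number of subjects.
#'
#' @param subjects List of [subject_record()] objects.
#' @param bounds [param_bounds()] covering the model's parameters.
#' @param model_kind 1 (one-compartment) or 2 (two-compartment).
#' @param em [error_model()].
#' @param control [npod_control()] settings.
#' @return An object of class `npml_result`: list with `grid`, `weights`,
#'   `loglik`, `loglik_trace` (post-solve log-likelihood after the
#'   initial grid and after each cycle), `cycles`, `converged`,
#'   `model_kind`, `bounds`, `n_subjects`.
#' @export
npod_fit <- function(subjects, bounds, model_kind = 1L, em = error_model(),
                     control = npod_control()) {
  stopifnot(length(subjects) >= 1, inherits(bounds, "param_bounds"))
  wanted <- model_param_names(model_kind)
  if (!identical(names(bounds), wanted))
    stop("bounds must name exactly: ", paste(wanted, collapse = ", "))
  subjects <- prepare_subjects(subjects)
  n <- length(subjects)

  solve_on <- function(grid) {
    log_psi <- log_likelihood_matrix(subjects, grid, em, model_kind)
    check_underflow(log_psi, control$underflow)
    ws <- optimize_weights(log_psi, kkt_tol = control$kkt_tol)
    cond <- condense(grid, ws$weights, bounds,
                     weight_floor = control$weight_floor,
                     merge_tol = control$merge_tol)
    log_psi2 <- log_likelihood_matrix(subjects, cond$grid, em, model_kind)
    ws2 <- optimize_weights(log_psi2, kkt_tol = control$kkt_tol)
    list(grid = cond$grid, weights = ws2$weights, loglik = ws2$loglik)
  }

  cur <- solve_on(sobol_init(bounds, control$n_sobol))
  trace <- cur$loglik
  cycles <- 0L
  converged <- FALSE
  while (cycles < control$max_cycles) {
    cycles <- cycles + 1L
    cand <- refine_points(cur$grid, cur$weights, subjects, bounds, em,
                          model_kind, nm_maxeval = control$nm_maxeval,
                          dedup_tol = control$merge_tol)
    nxt <- solve_on(cand)
    if (nxt$loglik <= cur$loglik) { trace <- c(trace, cur$loglik)
      converged <- TRUE; break }
    improved <- nxt$loglik - cur$loglik
    cur <- nxt
    trace <- c(trace, cur$loglik)
    if (improved < control$tol) { converged <- TRUE; break }
  }
  if (nrow(cur$grid) > n) {
    top <- order(cur$weights, decreasing = TRUE)[seq_len(n)]
    grid <- cur$grid[top, , drop = FALSE]
    log_psi <- log_likelihood_matrix(subjects, grid, em, model_kind)
    ws <- optimize_weights(log_psi, kkt_tol = control$kkt_tol)
    cur <- list(grid = grid, weights = ws$weights, loglik = ws$loglik)
  }
  structure(list(grid = cur$grid, weights = cur$weights,
                 loglik = cur$loglik, loglik_trace = trace, cycles = cycles,
                 converged = converged, model_kind = as.integer(model_kind),
                 bounds = bounds, n_subjects = n), class = "npml_result")
}

#' @export
print.npml_result <- function(x, ...) {
  cat(sprintf(
    "<nonparametric ML fit> %d-compartment model, %d subjects\n",
    x$model_kind, x$n_subjects))
  cat(sprintf("  support points: %d   log-likelihood: %.4f\n",
              nrow(x$grid), x$loglik))
  cat(sprintf("  cycles: %d   converged: %s\n", x$cycles, x$converged))
  invisible(x)
}

#' Serialize a nonparametric fit
#'
#' Writes the support points and weights as CSV (one row per support
#' point: parameter columns plus `weight`) and a JSON sidecar with the
#' log-likelihood, cycle count, convergence flag, bounds and model kind.
#'
#' @param result An `npml_result` from [npod_fit()].
#' @param csv_path Output CSV path.
#' @param json_path Output JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_npml_result <- function(result, csv_path, json_path) {
  df <- as.data.frame(result$grid)
  df$weight <- result$weights
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  meta <- list(loglik = result$loglik, cycles = result$cycles,
               converged = result$converged,
               model_kind = result$model_kind,
               bounds = lapply(result$bounds, as.numeric),
               n_subjects = result$n_subjects)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
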