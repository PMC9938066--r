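#' One-compartment model parameters
#'
#' Parameters of a one-compartment model with first-order elimination:
#' elimination rate constant `ke` (1/h) and central volume of
#' distribution `v` (L). Concentration is central amount divided by `v`.
#'
#' @param ke Elimination rate constant (1/h), strictly positive.
#' @param v Central volume (L), strictly positive.
#' @return An object of class `params_1c`.
#' @export
#' @examples
#' params_1c(ke = 0.1, v = 50)
params_1c <- function(ke, v) {
  stopifnot(is.numeric(ke), length(ke) == 1L, is.finite(ke), ke > 0,
            is.numeric(v), length(v) == 1L, is.finite(v), v > 0)
  structure(list(ke = ke, v = v), class = c("params_1c", "pk_params"))
}

#' Two-compartment model parameters
#'
#' Parameters of a two-compartment model: elimination from the central
#' compartment at rate `ke`, central-to-peripheral transfer at `kcp`,
#' peripheral-to-central at `kpc` (all 1/h), and central volume `v` (L).
#'
#' @param ke Elimination rate constant (1/h).
#' @param v Central volume (L).
#' @param kcp Central-to-peripheral rate constant (1/h).
#' @param kpc Peripheral-to-central rate constant (1/h).
#' @return An object of class `params_2c`.
#' @export
params_2c <- function(ke, v, kcp, kpc) {
  vals <- c(ke = ke, v = v, kcp = kcp, kpc = kpc)
  stopifnot(is.numeric(vals), all(is.finite(vals)), all(vals > 0))
  structure(list(ke = ke, v = v, kcp = kcp, kpc = kpc),
            class = c("params_2c", "pk_params"))
}

#' @export
print.pk_params <- function(x, ...) {
  kind <- if (inherits(x, "params_1c")) "one-compartment" else "two-compartment"
  cat(sprintf("<%s parameters> %s\n", kind,
              paste(sprintf("%s = %g", names(x), unlist(x)), collapse = ", ")))
  invisible(x)
}

#' Dose event
#'
#' A dose administered to the central compartment. `duration = 0` encodes
#' an intravenous bolus (instantaneous jump in central amount);
#' `duration > 0` encodes a zero-order infusion at rate
#' `amount / duration` over `[start_time, start_time + duration]`.
#'
#' @param start_time Start of administration (h), non-negative.
#' @param amount Dose amount (mg), non-negative.
#' @param duration Infusion duration (h); 0 for a bolus.
#' @return An object of class `dose_event`.
#' @export
dose_event <- function(start_time, amount, duration = 0) {
  stopifnot(is.numeric(start_time), length(start_time) == 1L, start_time >= 0,
            is.numeric(amount), length(amount) == 1L, amount >= 0,
            is.numeric(duration), length(duration) == 1L, duration >= 0)
  structure(list(start_time = start_time, amount = amount,
                 duration = duration), class = "dose_event")
}

#' Concentration observation
#'
#' @param time Observation time (h), non-negative.
#' @param value Measured concentration (mg/L); may be `NA` for a design
#'   point whose value is yet to be simulated.
#' @return An object of class `observation`.
#' @export
observation <- function(time, value = NA_real_) {
  stopifnot(is.numeric(time), length(time) == 1L, time >= 0)
  structure(list(time = time, value = as.numeric(value)),
            class = "observation")
}

#' Subject record
#'
#' One subject's dosing history and timed concentration observations.
#' Observations are sorted by time; at least one observation is required.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param doses List of [dose_event()] objects.
#' @param observations List of [observation()] objects.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, doses, observations) {
  stopifnot(length(subject_id) == 1L)
  stopifnot(is.list(doses), all(vapply(doses, inherits, TRUE, "dose_event")))
  stopifnot(is.list(observations), length(observations) >= 1L,
            all(vapply(observations, inherits, TRUE, "observation")))
  times <- vapply(observations, `[[`, 0, "time")
  observations <- observations[order(times)]
  structure(list(subject_id = as.character(subject_id), doses = doses,
                 observations = observations), class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject %s> %d dose(s), %d observation(s)\n",
              x$subject_id, length(x$doses), length(x$observations)))
  invisible(x)
}

obs_times <- function(subject) {
  vapply(subject$observations, `[[`, 0, "time")
}

obs_values <- function(subject) {
  vapply(subject$observations, `[[`, 0, "value")
}

#' Disposition eigenrates of the two-compartment model
#'
#' The two exponential rates governing drug disposition, i.e. the negated
#' eigenvalues of the rate matrix
#' `[[-(ke+kcp), kpc], [kcp, -kpc]]`:
#' `(ke + kcp + kpc +/- sqrt((ke + kcp + kpc)^2 - 4 ke kpc)) / 2`.
#'
#' @param p A [params_2c()] object.
#' @return Numeric vector `c(lambda1, lambda2)` with
#'   `lambda1 >= lambda2 > 0`.
#' @export
eigenrates <- function(p) {
  stopifnot(inherits(p, "params_2c"))
  s <- p$ke + p$kcp + p$kpc
  disc <- s^2 - 4 * p$ke * p$kpc
  root <- sqrt(max(disc, 0))  # >= 0 analytically for positive rates
  c(lambda1 = (s + root) / 2, lambda2 = (s - root) / 2)
}

#' Analytic one-compartment kinetics over one interval
#'
#' Amount of drug in the central compartment after time `t` under a
#' constant zero-order input `rate` and first-order elimination:
#' `X(t) = X(0) exp(-ke t) + (rate/ke) (1 - exp(-ke t))`.
#'
#' @param p A [params_1c()] object.
#' @param x0 Initial central amount (mg).
#' @param rate Constant infusion rate (mg/h) over the interval.
#' @param t Elapsed time (h); may be a vector.
#' @return Central amount(s) (mg), same length as `t`.
#' @export
simulate_1c <- function(p, x0, rate, t) {
  stopifnot(inherits(p, "params_1c"), all(t >= 0))
  e <- exp(-p$ke * t)
  pmax(x0 * e + (rate / p$ke) * (1 - e), 0)
}

#' Analytic two-compartment kinetics over one interval
#'
#' Amounts in the central and peripheral compartments after time `t`,
#' starting from `(xc0, xp0)` with constant zero-order input `rate` into
#' the central compartment. Computed from the eigendecomposition of the
#' rate matrix `A = [[-(ke+kcp), kpc], [kcp, -kpc]]`:
#' `X(t) = Xss + exp(At) (X0 - Xss)` with `Xss = -A^{-1} b`, `b = (rate, 0)`.
#'
#' @param p A [params_2c()] object.
#' @param xc0,xp0 Initial central and peripheral amounts (mg).
#' @param rate Constant infusion rate (mg/h) over the interval.
#' @param t Elapsed time (h); may be a vector.
#' @return A matrix with columns `xc` and `xp`, one row per element of `t`.
#' @export
simulate_2c <- function(p, xc0, xp0, rate, t) {
  stopifnot(inherits(p, "params_2c"), all(t >= 0))
  lam <- eigenrates(p)
  l1 <- lam[[1]]; l2 <- lam[[2]]
  a11 <- -(p$ke + p$kcp); a12 <- p$kpc
  a21 <- p$kcp;           a22 <- -p$kpc
  # steady-state (particular) solution: A xss = -b, b = (rate, 0)
  det_a <- p$ke * p$kpc
  xss_c <- rate / p$ke
  xss_p <- rate * p$kcp / det_a
  dc0 <- xc0 - xss_c
  dp0 <- xp0 - xss_p
  n <- length(t)
  if (abs(l1 - l2) > 1e-9 * l1) {
    # exp(At) = (e^{-l2 t}(A + l1 I) - e^{-l1 t}(A + l2 I)) / (l1 - l2)
    e1 <- exp(-l1 * t); e2 <- exp(-l2 * t)
    d <- l1 - l2
    m11 <- (e2 * (a11 + l1) - e1 * (a11 + l2)) / d
    m12 <- (e2 - e1) * a12 / d
    m21 <- (e2 - e1) * a21 / d
    m22 <- (e2 * (a22 + l1) - e1 * (a22 + l2)) / d
  } else {
    # repeated root: exp(At) = e^{-l t}(I + (A + l I) t)
    l <- (l1 + l2) / 2
    el <- exp(-l * t)
    m11 <- el * (1 + (a11 + l) * t)
    m12 <- el * a12 * t
    m21 <- el * a21 * t
    m22 <- el * (1 + (a22 + l) * t)
  }
  xc <- pmax(xss_c + m11 * dc0 + m12 * dp0, 0)
  xp <- pmax(xss_p + m21 * dc0 + m22 * dp0, 0)
  cbind(xc = xc, xp = xp)
}

# advance the compartment state vector by dt under constant input rate
propagate_state <- function(params, state, rate, dt) {
  if (dt <= 0) return(state)
  if (inherits(params, "params_1c")) {
    c(simulate_1c(params, state[[1]], rate, dt))
  } else {
    drop(simulate_2c(params, state[[1]], state[[2]], rate, dt))
  }
}

#' Predict concentrations at a subject's observation times
#'
#' Propagates the analytic compartment solutions piecewise across the
#' subject's dose events (bolus jumps and zero-order infusions, possibly
#' overlapping), carrying all compartment amounts forward between event
#' boundaries, and evaluates concentration (central amount / `v`) at each
#' observation time. A bolus at an observation time is applied before the
#' observation is read.
#'
#' @param subject A [subject_record()].
#' @param params A [params_1c()] or [params_2c()] object.
#' @return Numeric vector of predicted concentrations (mg/L), one per
#'   observation, in time order.
#' @export
predict_profile <- function(subject, params) {
  stopifnot(inherits(subject, "subject_record"), inherits(params, "pk_params"))
  t_obs <- obs_times(subject)
  n_cmt <- if (inherits(params, "params_1c")) 1L else 2L
  boluses <- list(); inf_start <- c(); inf_end <- c(); inf_rate <- c()
  bol_time <- c(); bol_amt <- c()
  for (d in subject$doses) {
    if (d$duration == 0) {
      bol_time <- c(bol_time, d$start_time)
      bol_amt <- c(bol_amt, d$amount)
    } else {
      inf_start <- c(inf_start, d$start_time)
      inf_end <- c(inf_end, d$start_time + d$duration)
      inf_rate <- c(inf_rate, d$amount / d$duration)
    }
  }
  breaks <- sort(unique(c(0, bol_time, inf_start, inf_end, t_obs)))
  state <- rep(0, n_cmt)
  pred <- numeric(length(t_obs))
  for (j in seq_along(breaks)) {
    tj <- breaks[j]
    if (length(bol_time))
      state[1] <- state[1] + sum(bol_amt[bol_time == tj])
    hit <- which(t_obs == tj)
    if (length(hit)) pred[hit] <- state[1] / params$v
    if (j < length(breaks)) {
      tnext <- breaks[j + 1]
      rate <- if (length(inf_start))
        sum(inf_rate[inf_start <= tj & inf_end >= tnext]) else 0
      state <- propagate_state(params, state, rate, tnext - tj)
    }
  }
  pred
}

model_param_names <- function(model_kind) {
  if (model_kind == 1L) c("ke", "v") else c("ke", "v", "kcp", "kpc")
}

params_from_vector <- function(x, model_kind) {
  if (model_kind == 1L) params_1c(x[[1]], x[[2]])
  else params_2c(x[[1]], x[[2]], x[[3]], x[[4]])
}
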