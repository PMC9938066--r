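# Synthetic population generator: truncated-mixture parameter
# distributions with outlier substitution, forward simulation through the
# analytic models and polynomial observation noise, retaining ground
# truth for recovery experiments.

#' Truncated-mixture specification for one parameter
#'
#' @param means,sds,fractions Component means, standard deviations and
#'   mixing fractions (fractions must sum to 1).
#' @param range Length-2 truncation interval; sampled values always fall
#'   inside it.
#' @return A list of class `mixture_spec`.
#' @export
mixture_spec <- function(means, sds, fractions = rep(1 / length(means),
                                                     length(means)),
                         range) {
  stopifnot(length(means) == length(sds), length(means) == length(fractions),
            abs(sum(fractions) - 1) < 1e-8, all(sds >= 0),
            length(range) == 2L, range[1] < range[2])
  structure(list(means = means, sds = sds, fractions = fractions,
                 range = as.numeric(range)), class = "mixture_spec")
}

#' Synthetic population specification
#'
#' Describes the population to emulate: a mixture distribution per PK
#' parameter (allowing unimodal and bimodal shapes), an outlier fraction
#' with its own generating distributions, a dosing regimen, observation
#' times and assay noise. The default is a 20-subject one-compartment
#' population with bimodal `ke` (modes 0.25 and 0.7, SD 0.05, truncated
#' to `[0, 1]`), `v ~ N(120, 25)` truncated to `[50, 200]`, one subject
#' in twenty replaced by a high-`ke` outlier near 0.95, a single 600 mg
#' 1-hour infusion and sampling at 1, 2, 4, 6, 8, 12 and 24 h.
#'
#' @param n_subjects Number of subjects.
#' @param model_kind 1 or 2.
#' @param parameters Named list of [mixture_spec()] objects, one per
#'   model parameter.
#' @param outlier_fraction Fraction of subjects replaced by outliers
#'   (in `[0, 0.5)`); the substituted count is `round(fraction * n)`.
#' @param outlier_parameters Named list of [mixture_spec()] objects used
#'   for outlier subjects (defaults to `parameters` for any parameter not
#'   listed).
#' @param doses List of [dose_event()] objects shared by all subjects.
#' @param obs_times Observation times (h).
#' @param em [error_model()] used to simulate observation noise.
#' @param conc_floor Lower clamp for simulated concentrations.
#' @param seed RNG seed.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(
    n_subjects = 20L, model_kind = 1L,
    parameters = list(
      ke = mixture_spec(means = c(0.25, 0.7), sds = c(0.05, 0.05),
                        fractions = c(0.5, 0.5), range = c(0, 1)),
      v = mixture_spec(means = 120, sds = 25, range = c(50, 200))),
    outlier_fraction = 0.05,
    outlier_parameters = list(
      ke = mixture_spec(means = 0.95, sds = 0.02, range = c(0, 1))),
    doses = list(dose_event(0, 600, 1)),
    obs_times = c(1, 2, 4, 6, 8, 12, 24),
    em = error_model(), conc_floor = 0, seed = 42L) {
  stopifnot(n_subjects >= 1, model_kind %in% c(1L, 2L),
            outlier_fraction >= 0, outlier_fraction < 0.5,
            identical(sort(names(parameters)),
                      sort(model_param_names(model_kind))),
            all(vapply(parameters, inherits, TRUE, "mixture_spec")),
            length(obs_times) >= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 model_kind = as.integer(model_kind),
                 parameters = parameters,
                 outlier_fraction = outlier_fraction,
                 outlier_parameters = outlier_parameters,
                 doses = doses, obs_times = sort(obs_times), em = em,
                 conc_floor = conc_floor, seed = as.integer(seed)),
            class = "population_spec")
}

rtrunc_norm1 <- function(mean, sd, range) {
  if (sd == 0) return(min(max(mean, range[1]), range[2]))
  for (i in 1:10000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= range[1] && x <= range[2]) return(x)
  }
  min(max(mean, range[1]), range[2])  # unreachable for sane specs
}

rmixture1 <- function(ms) {
  comp <- if (length(ms$fractions) == 1L) 1L
  else sample.int(length(ms$fractions), 1L, prob = ms$fractions)
  rtrunc_norm1(ms$means[comp], ms$sds[comp], ms$range)
}

#' Sample subject-level parameters
#'
#' Draws one parameter vector per subject from the truncated mixtures,
#' then substitutes `round(outlier_fraction * n)` randomly chosen
#' subjects with draws from the outlier distributions. Reproducible for
#' a fixed RNG state; callers wanting the spec's seed should
#' `set.seed(spec$seed)` first (as [generate_population()] does).
#'
#' @param spec A [population_spec()].
#' @return Data frame with one named column per parameter, plus a logical
#'   `outlier` column; one row per subject.
#' @export
sample_parameters <- function(spec) {
  pn <- model_param_names(spec$model_kind)
  draws <- matrix(NA_real_, spec$n_subjects, length(pn),
                  dimnames = list(NULL, pn))
  for (i in seq_len(spec$n_subjects))
    for (p in pn)
      draws[i, p] <- rmixture1(spec$parameters[[p]])
  n_out <- round(spec$outlier_fraction * spec$n_subjects)
  is_out <- rep(FALSE, spec$n_subjects)
  if (n_out > 0) {
    idx <- sample.int(spec$n_subjects, n_out)
    is_out[idx] <- TRUE
    for (i in idx)
      for (p in pn) {
        ms <- spec$outlier_parameters[[p]]
        if (is.null(ms)) ms <- spec$parameters[[p]]
        draws[i, p] <- rmixture1(ms)
      }
  }
  out <- as.data.frame(draws)
  out$outlier <- is_out
  out
}

#' Generate a synthetic population with ground truth
#'
#' Samples subject parameters (see [sample_parameters()]), simulates each
#' subject's concentration profile through the analytic model, and adds
#' independent Normal noise with SD from the error polynomial evaluated
#' at the noiseless prediction; simulated concentrations are clamped at
#' `spec$conc_floor`. The spec's seed makes the output fully
#' deterministic.
#'
#' @param spec A [population_spec()].
#' @return A list of class `true_population`: `subjects` (list of
#'   [subject_record()]), `true_params` (data frame with `subject_id`,
#'   parameter columns and `outlier`) and `spec`.
#' @export
generate_population <- function(spec) {
  set.seed(spec$seed)
  pars <- sample_parameters(spec)
  subjects <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    params <- params_from_vector(as.numeric(pars[i, model_param_names(
      spec$model_kind)]), spec$model_kind)
    skeleton <- subject_record(
      sprintf("S%03d", i), spec$doses,
      lapply(spec$obs_times, observation))
    pred <- predict_profile(skeleton, params)
    sd <- error_sd(spec$em, pred)
    y <- pmax(pred + stats::rnorm(length(pred), 0, sd), spec$conc_floor)
    subjects[[i]] <- subject_record(
      sprintf("S%03d", i), spec$doses,
      mapply(observation, spec$obs_times, y, SIMPLIFY = FALSE))
  }
  truth <- cbind(data.frame(subject_id = sprintf("S%03d",
                                                 seq_len(spec$n_subjects))),
                 pars)
  structure(list(subjects = subjects, true_params = truth, spec = spec),
            class = "true_population")
}

#' @export
print.true_population <- function(x, ...) {
  cat(sprintf(
    "<synthetic population> %d subjects, %d-compartment model, %d outlier(s)\n",
    length(x$subjects), x$spec$model_kind, sum(x$true_params$outlier)))
  invisible(x)
}

#' Write a synthetic population to disk
#'
#' Emits the standard event-format dataset CSV, a `truth.csv` with the
#' per-subject true parameters, and the generating spec echoed as JSON.
#'
#' @param pop A `true_population` from [generate_population()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dataset <- file.path(dir, "dataset.csv")
  truth <- file.path(dir, "truth.csv")
  specj <- file.path(dir, "population-spec.json")
  write_pk_dataset(pop$subjects, dataset)
  utils::write.csv(pop$true_params, truth, row.names = FALSE, quote = FALSE)
  spec <- pop$spec
  echo <- list(
    n_subjects = spec$n_subjects, model_kind = spec$model_kind,
    parameters = lapply(spec$parameters, unclass),
    outlier_fraction = spec$outlier_fraction,
    outlier_parameters = lapply(spec$outlier_parameters, unclass),
    doses = lapply(spec$doses, unclass),
    obs_times = spec$obs_times, error_coefficients = spec$em$coef,
    conc_floor = spec$conc_floor, seed = spec$seed)
  jsonlite::write_json(echo, specj, auto_unbox = TRUE, digits = NA)
  invisible(c(dataset = dataset, truth = truth, spec = specj))
}
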