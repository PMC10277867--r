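#' @title Synthetic observed-profile generator
#' @name synthetic_data
#' @description Forward-simulates a truth model and samples it on a
#'   sparse clinical grid with mean-unbiased multiplicative log-normal
#'   noise, emulating the statistical structure of digitized clinical
#'   concentration data so that calibration, qualification and population
#'   stages are testable without any external download. The truth
#'   parameters travel in a sidecar that the fitting path never reads.
NULL

.default_clinical_grid <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 24, 48)

#' Specification of a synthetic observed dataset
#'
#' @param compound compound name
#' @param dose_mg dose, mg
#' @param sampling_times increasing sampling grid, h
#' @param noise_cv multiplicative log-normal coefficient of variation
#' @param n_replicates replicate profiles per time point
#' @param seed integer seed (generation is deterministic given the spec)
#' @param truth_overrides named list of true parameter values used in the
#'   generating model (e.g. `list(peff = 6.7, rbp = 0.55)`)
#' @return object of class `synthetic_spec`
#' @export
synthetic_spec <- function(compound, dose_mg,
                           sampling_times = .default_clinical_grid,
                           noise_cv = 0.15, n_replicates = 1, seed = 1,
                           truth_overrides = list()) {
  stopifnot(all(diff(sampling_times) > 0), noise_cv >= 0, n_replicates >= 1)
  structure(list(compound = tolower(compound), dose_mg = dose_mg,
                 sampling_times = sampling_times, noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 truth_overrides = truth_overrides),
            class = "synthetic_spec")
}

#' Generate a synthetic observed dataset
#'
#' Simulates the truth model, samples it at the spec's times and applies
#' `exp(sigma Z - sigma^2/2)` noise (mean-unbiased: the expectation of
#' each observation equals the simulated truth), with
#' `sigma^2 = log(1 + cv^2)`.
#'
#' @param spec a [synthetic_spec()]
#' @param dir optional directory; when given, writes
#'   `observed_profile.csv` and `truth.json` there
#' @return list: `observations` (data.frame `time_h`,
#'   `concentration_ng_ml`, `replicate_id`), `truth` (list: parameters
#'   and the noise-free sampled profile)
#' @export
generate_synthetic <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sim <- .sim_with_params(spec$compound, spec$dose_mg,
                          spec$truth_overrides,
                          grid = sort(unique(c(0, spec$sampling_times))),
                          rtol = 1e-8, atol = 1e-10)
  truth_conc <- approx(sim$time, sim$plasma_concentration,
                       xout = spec$sampling_times)$y
  sigma <- sqrt(log(1 + spec$noise_cv^2))
  obs <- with_seed(spec$seed, {
    do.call(rbind, lapply(seq_len(spec$n_replicates), function(r) {
      eps <- rnorm(length(truth_conc), 0, sigma)
      mult <- if (sigma > 0) exp(eps - sigma^2 / 2) else rep(1, length(eps))
      data.frame(time_h = spec$sampling_times,
                 concentration_ng_ml = truth_conc * mult,
                 replicate_id = r)
    }))
  })
  truth <- list(compound = spec$compound, dose_mg = spec$dose_mg,
                parameters = spec$truth_overrides,
                noise_cv = spec$noise_cv, seed = spec$seed,
                sampled_truth = data.frame(
                  time_h = spec$sampling_times,
                  concentration_ng_ml = truth_conc))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(obs, file.path(dir, "observed_profile.csv"),
              row.names = FALSE)
    jsonlite::write_json(truth[names(truth) != "sampled_truth"],
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  list(observations = obs, truth = truth)
}

#' Read an observed-profile CSV
#'
#' One reader for synthetic and user-supplied profiles (columns `time_h`,
#' `concentration_ng_ml`, optional `replicate_id`).
#' @param path CSV path
#' @return data.frame
#' @export
read_observed_profile <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "concentration_ng_ml")
  if (!all(need %in% names(out))) {
    stop("observed-profile CSV must have columns ",
         paste(need, collapse = ", "))
  }
  out
}

#' Generate-then-fit parameter recovery experiment
#'
#' End-to-end check of the calibration stage: synthetic observations are
#' generated at known true parameter values, the same parameters are then
#' re-estimated from the noisy data alone (the truth sidecar is not
#' passed to the fit), and the relative recovery errors are reported.
#'
#' @param spec a [synthetic_spec()] whose `truth_overrides` contain every
#'   parameter named in `free`
#' @param free parameters to recover
#' @param base_params fixed overrides shared by generation and fit
#' @param ... passed to [fit_parameters()] (`n_starts`, `seed`, `maxit`)
#' @return list: `truth`, `estimate`, `relative_error`, `fit`
#' @export
recovery_harness <- function(spec, free = names(spec$truth_overrides),
                             base_params = list(), ...) {
  if (!all(free %in% names(spec$truth_overrides))) {
    stop("free parameters must be present in truth_overrides")
  }
  spec$truth_overrides <- modifyList(base_params, spec$truth_overrides)
  gen <- generate_synthetic(spec)
  fit <- fit_parameters(spec$compound, spec$dose_mg, gen$observations,
                        free = free, base_params = base_params, ...)
  truth <- unlist(spec$truth_overrides[free])
  est <- fit$estimate[free]
  rel <- (est - truth) / truth
  list(truth = truth, estimate = est, relative_error = rel, fit = fit)
}
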