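#' @title Virtual-population prediction band of urinary drug excretion
#' @name population
#' @description Runs one simulation per sampled virtual subject
#'   (physiological variability only; compound parameters fixed) and
#'   summarizes cumulative urinary drug excretion as pointwise 5th/50th/
#'   95th percentile curves -- the 90% prediction band that the renal
#'   model is checked against.
NULL

#' Simulate a virtual population
#'
#' @param compound name or `compound_record`
#' @param dose_mg dose, mg (single oral dose)
#' @param pop a [population_spec()]
#' @param params calibrated parameter overrides (default:
#'   [calibrated_params()] of the compound)
#' @param grid output time grid, h
#' @param rtol,atol solver tolerances for the per-subject runs
#' @return object of class `population_band`: `time`, `p5`, `p50`, `p95`
#'   (mg), `endpoints` (per-subject final amounts), `n_subjects`, `seed`,
#'   `excluded` (count of failed subject simulations)
#' @export
simulate_population <- function(compound, dose_mg, pop = population_spec(),
                                params = NULL,
                                grid = seq(0, 48, by = 0.25),
                                rtol = 1e-6, atol = 1e-9) {
  name <- if (inherits(compound, "compound_record")) compound$name
          else tolower(compound)
  if (is.null(params)) params <- calibrated_params(name)
  subjects <- sample_population(pop)
  curves <- matrix(NA_real_, nrow = length(grid), ncol = length(subjects))
  ok <- logical(length(subjects))
  for (i in seq_along(subjects)) {
    res <- tryCatch(
      .sim_with_params(compound, dose_mg, params, subject = subjects[[i]],
                       grid = grid, rtol = rtol, atol = atol),
      error = function(e) NULL)
    if (!is.null(res)) {
      curves[, i] <- res$cumulative_urinary_excretion
      ok[i] <- TRUE
    }
  }
  excluded <- sum(!ok)
  if (excluded > 0.05 * length(subjects)) {
    warning(excluded, " of ", length(subjects),
            " subject simulations failed and were excluded")
  }
  curves <- curves[, ok, drop = FALSE]
  qs <- apply(curves, 1, quantile, probs = c(0.05, 0.5, 0.95), type = 7)
  structure(list(time = grid, p5 = qs[1, ], p50 = qs[2, ], p95 = qs[3, ],
                 endpoints = curves[nrow(curves), ],
                 curves = curves,
                 n_subjects = sum(ok), seed = pop$seed,
                 excluded = excluded,
                 compound = name, dose_mg = dose_mg),
            class = "population_band")
}

#' @export
print.population_band <- function(x, ...) {
  cat(sprintf("<population_band> %s %.4g mg, n = %d (seed %d)\n",
              x$compound, x$dose_mg, x$n_subjects, x$seed))
  cat(sprintf("  cumulative urinary excretion at %.0f h: %.3g [%.3g, %.3g] mg\n",
              max(x$time), x$p50[length(x$p50)], x$p5[length(x$p5)],
              x$p95[length(x$p95)]))
  invisible(x)
}

#' Fraction of observed points inside the population band
#'
#' Band edges are linearly interpolated at the observed times.
#'
#' @param band a `population_band`
#' @param observed data.frame with columns `time_h`, `amount_mg`
#' @return list: `coverage` (fraction in \[0,1\]), `inside` (per-point
#'   logical)
#' @export
coverage_check <- function(band, observed) {
  stopifnot(all(c("time_h", "amount_mg") %in% names(observed)))
  if (nrow(observed) == 0) stop("empty observed series")
  if (any(observed$time_h < min(band$time) |
          observed$time_h > max(band$time))) {
    stop("observed times outside the band's time span")
  }
  lo <- approx(band$time, band$p5, xout = observed$time_h)$y
  hi <- approx(band$time, band$p95, xout = observed$time_h)$y
  inside <- observed$amount_mg >= lo & observed$amount_mg <= hi
  list(coverage = mean(inside), inside = inside)
}
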