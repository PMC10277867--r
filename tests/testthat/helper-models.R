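# shared fixtures for the suite: calibrations and reference simulations
# are deterministic, so compute each at most once per test run

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

test_calibration <- function(compound) {
  cached(paste0("calib_", compound),
         suppressWarnings(calibrated_params(compound)))
}

# a quick simulation with moderate solver settings, cached by key
test_sim <- function(key, compound, dose_mg, params = list(),
                     grid = seq(0, 72, by = 0.1), ...) {
  cached(key, {
    spec <- build_model(compound, dose_mg, params = params,
                        solver = list(rtol = 1e-6, atol = 1e-9,
                                      grid = grid), ...)
    simulate_pbpk(spec)
  })
}
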