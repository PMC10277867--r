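#' @title Virtual subject physiology
#' @description The reference 70 kg adult (tissue volumes, plasma flows,
#'   glomerular filtration, gastrointestinal geometry, proximal-tubule
#'   fluid flows) and parametric sampling of virtual populations.
#' @name physiology
NULL

# Tissues drained directly into the venous pool; spleen and gut drain
# through the liver (portal), liver through the hepatic vein.
.venous_tissues <- c("heart", "brain", "muscle", "adipose", "skin",
                     "bone_rest", "kidney", "reproductive")
.portal_tissues <- c("spleen", "gut")
.all_tissues    <- c(.venous_tissues, .portal_tissues, "liver", "lung")

#' Reference adult subject
#'
#' A 70 kg adult with literature-standard tissue volumes and plasma flows
#' (shipped in `physiology.csv`), glomerular filtration rate 127
#' mL/min/1.73 m2, plasma glucose 5 mmol/L, fasted gastrointestinal
#' geometry, and proximal-tubule luminal flows of GFR x {1, 0.6, 0.4} at
#' the entry of segments S1/S2/S3 (about two thirds of filtered water is
#' reabsorbed along the proximal tubule).
#'
#' Flows are stored as fractions of cardiac plasma output so that the
#' venous return balance holds exactly by construction.
#'
#' @param body_weight_kg body weight (kg); volumes scale linearly and flows
#'   by the 3/4 power from the 70 kg reference
#' @param height_cm height (cm), used for body surface area
#' @param gfr glomerular filtration rate, mL/min/1.73 m2
#' @param plasma_glucose plasma glucose, mmol/L
#' @param cardiac_output_plasma_l_h cardiac plasma output at 70 kg, L/h
#' @param tubule_flow_fractions luminal flow entering S1, S2, S3 as
#'   fractions of volumetric GFR
#' @return an object of class `subject_physiology`
#' @export
#' @examples
#' sub <- reference_subject()
#' sub$gfr            # 127
#' sub$gfr_l_h        # volumetric filtration, L/h
reference_subject <- function(body_weight_kg = 70, height_cm = 170,
                              gfr = 127, plasma_glucose = 5,
                              cardiac_output_plasma_l_h = 172,
                              tubule_flow_fractions = c(S1 = 1, S2 = 0.6,
                                                        S3 = 0.4)) {
  stopifnot(body_weight_kg > 0, height_cm > 0, gfr > 0, plasma_glucose > 0)
  phys <- .read_fixture("physiology.csv")
  geom <- .read_fixture("acat_geometry.csv")

  wt_ratio <- body_weight_kg / 70
  vols  <- setNames(phys$volume_l * wt_ratio, phys$tissue)
  co    <- cardiac_output_plasma_l_h * wt_ratio^0.75
  fr    <- setNames(phys$flow_frac_co, phys$tissue)
  flows <- fr[.all_tissues] * co
  flows["lung"] <- co

  bsa <- 0.007184 * body_weight_kg^0.425 * height_cm^0.725  # Du Bois, m2
  gfr_l_h <- gfr * (bsa / 1.73) * 60 / 1000                 # L/h

  sub <- structure(list(
    body_weight       = body_weight_kg,
    height_cm         = height_cm,
    body_surface_area = bsa,
    tissue_volumes    = vols,             # L, includes arterial/venous
    plasma_flows      = flows,            # L/h, named by tissue
    cardiac_output    = co,               # L/h plasma
    gfr               = gfr,              # mL/min/1.73 m2
    gfr_l_h           = gfr_l_h,
    plasma_glucose    = plasma_glucose,   # mmol/L
    gi_geometry       = geom,
    tubule_flow_fractions = tubule_flow_fractions,
    tubule_flows      = tubule_flow_fractions * gfr_l_h  # L/h
  ), class = "subject_physiology")
  validate_subject(sub)
  sub
}

#' @export
print.subject_physiology <- function(x, ...) {
  cat(sprintf("<subject_physiology> %.1f kg, %.0f cm, BSA %.2f m2\n",
              x$body_weight, x$height_cm, x$body_surface_area))
  cat(sprintf("  cardiac plasma output %.1f L/h, GFR %.1f mL/min/1.73m2 (%.2f L/h)\n",
              x$cardiac_output, x$gfr, x$gfr_l_h))
  invisible(x)
}

validate_subject <- function(sub) {
  v <- sub$tissue_volumes
  q <- sub$plasma_flows
  stopifnot(all(v > 0), all(q > 0), sub$gfr_l_h > 0)
  frac <- sub$tubule_flow_fractions
  # non-increasing: water is reabsorbed (or, in the limiting no-
  # reabsorption configuration, flows are equal)
  stopifnot(length(frac) == 3, all(frac > 0), all(diff(frac) <= 0))
  # venous return: directly-draining tissues plus the hepatic vein
  # (liver outflow = hepatic artery + portal inflow) must equal cardiac output
  qh <- q["liver"] + sum(q[.portal_tissues])
  ret <- sum(q[.venous_tissues]) + qh
  if (abs(ret - sub$cardiac_output) / sub$cardiac_output > 1e-9) {
    stop("venous return does not balance cardiac output (residual ",
         format(abs(ret - sub$cardiac_output)), " L/h)")
  }
  invisible(TRUE)
}

#' Specification of a virtual population
#'
#' @param n_subjects number of virtual subjects (>= 1)
#' @param weight_mean,weight_sd body weight distribution, kg (normal,
#'   truncated at +/- 3 sd)
#' @param height_mean,height_sd height distribution, cm
#' @param gfr_mean geometric mean GFR, mL/min/1.73 m2
#' @param gfr_cv lognormal coefficient of variation of GFR
#' @param seed integer seed; population generation is a pure function of
#'   the spec including this seed
#' @return an object of class `population_spec`
#' @export
population_spec <- function(n_subjects = 100, weight_mean = 70,
                            weight_sd = 10, height_mean = 170,
                            height_sd = 7, gfr_mean = 127, gfr_cv = 0.15,
                            seed = 1L) {
  stopifnot(n_subjects >= 1, weight_sd >= 0, height_sd >= 0, gfr_cv >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 height_mean = height_mean, height_sd = height_sd,
                 gfr_mean = gfr_mean, gfr_cv = gfr_cv,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# evaluate expr with a private RNG stream so that callers' RNG state is
# untouched and results depend only on the given seed
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.rnorm_trunc <- function(n, mean, sd, k = 3) {
  if (sd == 0) return(rep(mean, n))
  x <- rnorm(n, mean, sd)
  bad <- abs(x - mean) > k * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > k * sd
  }
  x
}

#' Sample a virtual population
#'
#' Weight and height are drawn from truncated normal distributions, GFR
#' log-normally around its mean; tissue volumes scale linearly with weight
#' and plasma flows with the 3/4 power (allometric convention). The result
#' is a pure function of the spec (including its seed).
#'
#' @param spec a [population_spec()]
#' @return list of `subject_physiology`, length `spec$n_subjects`
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (spec$n_subjects < 1) stop("degenerate population: n_subjects < 1")
  with_seed(spec$seed, {
    w <- .rnorm_trunc(spec$n_subjects, spec$weight_mean, spec$weight_sd)
    h <- .rnorm_trunc(spec$n_subjects, spec$height_mean, spec$height_sd)
    sdlog <- sqrt(log(1 + spec$gfr_cv^2))
    g <- spec$gfr_mean * exp(rnorm(spec$n_subjects, -sdlog^2 / 2, sdlog))
    lapply(seq_len(spec$n_subjects), function(i) {
      reference_subject(body_weight_kg = w[i], height_cm = h[i], gfr = g[i])
    })
  })
}
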