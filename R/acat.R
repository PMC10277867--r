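#' @title Nine-compartment absorption and transit (ACAT) gut model
#' @name acat
#' @description Gastric emptying, first-order intestinal transit,
#'   Noyes-Whitney-form dissolution, permeability-driven absorption with
#'   per-segment absorption scale factors (ASF), and a lumped gut
#'   first-pass extraction on the absorbed flux. Luminal volumes are
#'   static per compartment; dissolved concentration is
#'   `dissolved_amount / luminal_volume`.
NULL

.gut_compartments <- c("stomach", "duodenum", "jejunum1", "jejunum2",
                       "ileum1", "ileum2", "ileum3", "caecum", "asc_colon")

#' Default absorption settings for a compound
#'
#' The per-segment absorption scale factor follows cylindrical
#' surface-to-volume scaling, `ASF_i = asf_coefficient * 2 / radius_i`,
#' with colonic compartments down-weighted by `colon_factor` (low fluid
#' and mucus-limited permeation). The stomach does not absorb. Transit
#' times default to the fasted literature standard: stomach 0.25 h, small
#' intestine 3.3 h split across the six segments by the pinned fractions
#' of `acat_geometry.csv`, caecum + ascending colon 13 h.
#'
#' The single `asf_coefficient` is the calibration handle that stands in
#' for a proprietary regional-absorption model: it preserves the role of
#' the ASF (per-segment weighting of permeability) while keeping one
#' interpretable knob per compound.
#'
#' @param compound a `compound_record`
#' @param subject a `subject_physiology` (supplies GI geometry)
#' @param asf_coefficient unitless global absorption calibration factor
#' @param stomach_transit_h gastric emptying time constant, h
#' @param small_intestine_transit_h total small-intestinal transit, h
#' @param colon_transit_h combined caecum + ascending colon transit, h
#' @param fraction_gut_extracted lumped first-pass extraction of absorbed
#'   drug before the portal vein, 0-1
#' @param dissolution_k dissolution rate coefficient, 1/h per (mg/mL) of
#'   solubility deficit
#' @param colon_factor down-weighting of colonic ASF
#' @return object of class `absorption_settings`
#' @export
default_absorption <- function(compound, subject = reference_subject(),
                               asf_coefficient = 1,
                               stomach_transit_h = 0.25,
                               small_intestine_transit_h = 3.3,
                               colon_transit_h = 13,
                               fraction_gut_extracted = 0,
                               dissolution_k = 30,
                               colon_factor = 0.1) {
  stopifnot(asf_coefficient >= 0, stomach_transit_h > 0,
            small_intestine_transit_h > 0, colon_transit_h > 0,
            fraction_gut_extracted >= 0, fraction_gut_extracted < 1,
            dissolution_k > 0)
  geom <- subject$gi_geometry
  rownames(geom) <- geom$compartment
  geom <- geom[.gut_compartments, ]
  asf <- ifelse(is.na(geom$radius_cm), 0,
                asf_coefficient * 2 / geom$radius_cm)
  names(asf) <- .gut_compartments
  asf[c("caecum", "asc_colon")] <- asf[c("caecum", "asc_colon")] * colon_factor

  si <- geom$sitt_fraction
  si_frac <- si[!is.na(si)] / sum(si[!is.na(si)])
  transit_h <- c(stomach_transit_h,
                 small_intestine_transit_h * si_frac,
                 colon_transit_h * c(4.5, 8.5) / 13)
  names(transit_h) <- .gut_compartments

  structure(list(
    asf = asf,                                   # 1/cm
    transit_h = transit_h,                       # per-compartment mean
    stomach_transit_h = stomach_transit_h,
    small_intestine_transit_h = small_intestine_transit_h,
    colon_transit_h = colon_transit_h,
    fraction_gut_extracted = fraction_gut_extracted,
    dissolution_k = dissolution_k,
    asf_coefficient = asf_coefficient,
    colon_factor = colon_factor,
    luminal_volume_ml = setNames(geom$volume_ml, .gut_compartments)
  ), class = "absorption_settings")
}

#' Time derivative of the gut luminal state
#'
#' Implements, per compartment i: first-order transit at rate `1/T_i`
#' acting on both undissolved and dissolved drug; dissolution at rate
#' `k_d * undissolved_i * (Cs - Cd_i)` (negative values re-precipitate, so
#' the dissolved concentration cannot exceed solubility); absorption flux
#' `Peff * ASF_i * dissolved_i` from the dissolved pool. Of the summed
#' absorbed flux, the fraction `(1 - fraction_gut_extracted)` enters the
#' portal vein.
#'
#' @param undissolved,dissolved mg per compartment (length 9, ordered
#'   stomach ... ascending colon)
#' @param settings an `absorption_settings`
#' @param compound a `compound_record`
#' @return list with `d_undissolved`, `d_dissolved` (mg/h), scalar rates
#'   `fecal_rate`, `absorbed_rate`, `portal_rate`, `extracted_rate`
#' @export
gut_derivs <- function(undissolved, dissolved, settings, compound) {
  if (any(undissolved < -1e-6) || any(dissolved < -1e-6)) {
    stop("negative gut state encountered; solver misconfiguration")
  }
  kt <- 1 / settings$transit_h
  vol <- settings$luminal_volume_ml
  cs <- compound$solubility                       # mg/mL
  cd <- dissolved / vol                           # mg/mL
  diss <- settings$dissolution_k * undissolved * (cs - cd)
  # no re-precipitation beyond the dissolved pool itself
  abs_flux <- compound$peff * settings$asf * dissolved   # mg/h

  tr_u <- kt * undissolved
  tr_d <- kt * dissolved
  shift <- function(x) c(0, x[-length(x)])
  d_u <- shift(tr_u) - tr_u - diss
  d_d <- shift(tr_d) - tr_d + diss - abs_flux

  absorbed_rate <- sum(abs_flux)
  g <- settings$fraction_gut_extracted
  list(d_undissolved = d_u,
       d_dissolved   = d_d,
       fecal_rate    = tr_u[9] + tr_d[9],
       absorbed_rate = absorbed_rate,
       portal_rate   = (1 - g) * absorbed_rate,
       extracted_rate = g * absorbed_rate)
}
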