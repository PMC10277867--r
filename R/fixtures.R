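#' @title Compound and clinical-PK fixtures
#' @description Readers for the versioned CSV fixtures shipped with the
#'   package: compound physicochemical/disposition parameters, observed and
#'   model-reported pharmacokinetic parameters per dose, and the maximum
#'   SGLT1 inhibition-ratio table. All downstream modules obtain their
#'   inputs through these readers, so units are normalized in one place.
#' @name fixtures
NULL

.sgltsim_compounds <- c("ertugliflozin", "empagliflozin", "henagliflozin",
                        "sotagliflozin")

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "sgltsim")
  if (path == "") {
    # during development (pkgload) inst/ may be on the path directly
    path <- system.file("inst", "extdata", file, package = "sgltsim")
  }
  if (path == "") stop("fixture file not found: ", file)
  path
}

.fixture_cache <- new.env(parent = emptyenv())

.read_fixture <- function(file) {
  if (!exists(file, envir = .fixture_cache)) {
    assign(file, read.csv(.extdata(file), stringsAsFactors = FALSE),
           envir = .fixture_cache)
  }
  get(file, envir = .fixture_cache)
}

#' Load one gliflozin's model parameters
#'
#' Returns the parameter record for one of the four compounds with units
#' normalized to the internal basis: effective permeability in cm/h,
#' unbound plasma fraction as 0-1, clearances in L/h/kg, solubility in the
#' unit named by its tag (default mg/mL), inhibition constants in nM.
#'
#' The printed solubility unit in the source table ("mg/L") is three orders
#' of magnitude below the known aqueous solubility of these compounds; the
#' fixture therefore carries an explicit unit tag, defaulting to mg/mL.
#'
#' @param name compound name (case-insensitive), one of ertugliflozin,
#'   empagliflozin, henagliflozin, sotagliflozin
#' @return an object of class `compound_record`
#' @export
#' @examples
#' cpd <- load_compound("ertugliflozin")
#' cpd$fup      # 0.064
#' cpd$ki_sglt2 # 0.88 nM
load_compound <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  key <- tolower(trimws(name))
  if (!key %in% .sgltsim_compounds) {
    stop("unknown compound '", name, "'; available: ",
         paste(.sgltsim_compounds, collapse = ", "), call. = FALSE)
  }
  tab <- .read_fixture("compounds.csv")
  row <- tab[tab$name == key, , drop = FALSE]
  sol_unit <- row$solubility_unit
  sol_mg_ml <- switch(sol_unit,
    "mg/mL" = row$solubility,
    "mg/L"  = row$solubility / 1000,
    stop("unrecognized solubility unit tag: ", sol_unit))
  rec <- list(
    name             = key,
    molecular_weight = row$molecular_weight,    # g/mol
    log_p            = row$log_p,
    solubility       = sol_mg_ml,               # mg/mL
    solubility_unit  = "mg/mL",
    solubility_printed = row$solubility,        # as in the source table
    peff             = row$peff_1e4_cm_s * 1e-4 * 3600, # cm/h
    peff_1e4_cm_s    = row$peff_1e4_cm_s,
    fup              = row$fup,
    rbp              = row$rbp,
    cl_total         = row$cl_total,            # L/h/kg
    cl_hepatic       = row$cl_hepatic,          # L/h/kg
    ki_sglt1         = row$ki_sglt1_nm,         # nM
    ki_sglt2         = row$ki_sglt2_nm          # nM
  )
  validate_compound(rec)
  structure(rec, class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record> %s\n", x$name))
  cat(sprintf("  MW %.1f g/mol, logP %.2f, solubility %.4g mg/mL\n",
              x$molecular_weight, x$log_p, x$solubility))
  cat(sprintf("  Peff %.3g cm/h, fup %.3f, Rbp %.2f\n",
              x$peff, x$fup, x$rbp))
  cat(sprintf("  CL total %.2f, hepatic %.2f L/h/kg\n",
              x$cl_total, x$cl_hepatic))
  cat(sprintf("  Ki SGLT1 %.4g nM, SGLT2 %.4g nM\n",
              x$ki_sglt1, x$ki_sglt2))
  invisible(x)
}

validate_compound <- function(rec) {
  with(rec, {
    stopifnot(fup > 0, fup <= 1, rbp > 0, peff > 0,
              cl_hepatic <= cl_total + 1e-12,
              ki_sglt1 > 0, ki_sglt2 > 0,
              solubility > 0, molecular_weight > 0)
  })
  invisible(TRUE)
}

#' Construct an oral dose regimen
#'
#' @param dose_mg dose per administration, mg
#' @param n_doses number of administrations (1 = single dose)
#' @param interval_h dosing interval in hours, required when `n_doses > 1`
#' @param body_weight_kg body weight used to scale per-kg clearances
#' @return an object of class `dose_regimen`
#' @export
dose_regimen <- function(dose_mg, n_doses = 1L, interval_h = 24,
                         body_weight_kg = 70) {
  # dose 0 is admitted for null-input checks (all-zero trajectories)
  stopifnot(dose_mg >= 0, n_doses >= 1, body_weight_kg > 0)
  if (n_doses > 1 && !(interval_h > 0)) {
    stop("interval_h must be positive for multiple dosing")
  }
  structure(list(dose_mg = dose_mg, route = "oral",
                 n_doses = as.integer(n_doses), interval_h = interval_h,
                 body_weight_kg = body_weight_kg),
            class = "dose_regimen")
}

#' Load observed pharmacokinetic parameters for a compound
#'
#' Observed AUC (ng.h/mL), Cmax (ng/mL) and Tmax (h) per printed dose level,
#' as collected from the single-dose clinical studies.
#'
#' @param compound compound name (case-insensitive)
#' @return data.frame with one row per dose
#' @export
load_observed_pk <- function(compound) {
  key <- tolower(trimws(compound))
  if (!key %in% .sgltsim_compounds) {
    stop("unknown compound '", compound, "'; available: ",
         paste(.sgltsim_compounds, collapse = ", "), call. = FALSE)
  }
  tab <- .read_fixture("observed_pk.csv")
  out <- tab[tab$compound == key, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load the source model's reported (predicted) PK parameters
#'
#' The reference predictions that accompany the observed table; used only
#' for cross-checks and reporting, never as model input.
#' @inheritParams load_observed_pk
#' @return data.frame with one row per dose
#' @export
load_reference_predicted_pk <- function(compound) {
  key <- tolower(trimws(compound))
  if (!key %in% .sgltsim_compounds) {
    stop("unknown compound '", compound, "'", call. = FALSE)
  }
  tab <- .read_fixture("predicted_pk.csv")
  out <- tab[tab$compound == key, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load the reported maximum SGLT1 inhibition-ratio table
#'
#' Maximum inhibition ratios (%) on SGLT1 in the duodenum, jejunum I and
#' renal S3 segment per compound and dose, as printed in the source table
#' (the ertugliflozin/henagliflozin column doses are stored as printed).
#'
#' @return data.frame with columns site, compound, dose_mg, max_ratio_pct
#' @export
load_inhibition_max <- function() {
  .read_fixture("inhibition_max.csv")
}

#' Lowest printed dose per compound, used for model calibration
#' @return named numeric vector (mg)
#' @export
calibration_doses <- function() {
  c(ertugliflozin = 1, empagliflozin = 1, henagliflozin = 2.5,
    sotagliflozin = 200)
}

#' Highest approved dose per compound
#' @return named numeric vector (mg)
#' @export
approved_doses <- function() {
  c(ertugliflozin = 15, empagliflozin = 25, henagliflozin = 10,
    sotagliflozin = 400)
}
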