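#' @title Proximal-tubule drug and glucose handling
#' @name tubule
#' @description Quasi-steady-state submodel of the S1/S2/S3 proximal
#'   tubule segments. Tubular transit (~ minutes) is fast relative to
#'   plasma kinetics (hours), so segment concentrations are algebraic
#'   functions of the instantaneous plasma concentration and luminal
#'   fluid flows. Drug is filtered (GFR x fup), neither secreted nor
#'   reabsorbed, and concentrates as water is reabsorbed along the
#'   tubule. Filtered glucose is reabsorbed by SGLT2 in S1/S2 and SGLT1
#'   in S3 under competitive inhibition by the luminal drug; glucose
#'   escaping S3 is the urinary glucose excretion (UGE).
NULL

#' Glucose transport parameters of the proximal tubule
#'
#' Defaults place the total reabsorption capacity at 2.5 mmol/min split
#' about 90/10 between the low-affinity/high-capacity SGLT2 (Km 2 mmol/L,
#' S1/S2) and the high-affinity/low-capacity SGLT1 (Km 0.4 mmol/L, S3) --
#' systems-pharmacology literature values, configurable.
#'
#' @param vmax_sglt2,vmax_sglt1 maximal reabsorption rates, mmol/h
#' @param km_sglt2,km_sglt1 glucose affinity constants, mmol/L
#' @return object of class `glucose_params`
#' @export
glucose_params <- function(vmax_sglt2 = 135, km_sglt2 = 2,
                           vmax_sglt1 = 15, km_sglt1 = 0.4) {
  stopifnot(vmax_sglt2 > 0, km_sglt2 > 0, vmax_sglt1 > 0, km_sglt1 > 0)
  structure(list(vmax_sglt2 = vmax_sglt2, km_sglt2 = km_sglt2,
                 vmax_sglt1 = vmax_sglt1, km_sglt1 = km_sglt1),
            class = "glucose_params")
}

#' Drug concentration along the proximal tubule
#'
#' Filtered drug flow is `GFR_volumetric * fup * C_plasma`; the luminal
#' concentration in segment i is that flow divided by the luminal fluid
#' flow at the segment entry, so the concentration rises as water is
#' reabsorbed (filtrate convention; the inhibitor facing the apical
#' membrane is the luminal free drug).
#'
#' @param plasma_conc plasma concentration(s), ng/mL (vectorized)
#' @param compound a `compound_record`
#' @param subject a `subject_physiology`
#' @return matrix (length(plasma_conc) x 3) of segment drug
#'   concentrations, ng/mL, columns S1/S2/S3
#' @export
tubule_concentrations <- function(plasma_conc, compound, subject) {
  stopifnot(all(plasma_conc >= 0))
  frac <- subject$tubule_flow_fractions
  out <- outer(plasma_conc * compound$fup, 1 / frac)
  colnames(out) <- names(frac)
  out
}

#' Glucose reabsorption cascade with competitive inhibition
#'
#' Sequential S1 -> S2 -> S3 mass balance at one time point. Each of
#' S1/S2 carries half the SGLT2 capacity; S3 carries SGLT1. The segment
#' glucose concentration is `flux_in / flow`; the reabsorption rate is
#' the competitive-inhibition Michaelis-Menten rate, capped at the
#' incoming flux so that glucose is conserved exactly.
#'
#' @param subject a `subject_physiology` (supplies GFR, tubule flows and
#'   plasma glucose)
#' @param params a [glucose_params()]
#' @param inhibitor named/numeric vector of luminal drug concentration in
#'   S1, S2, S3 (nM); scalars are recycled
#' @param ki_sglt2,ki_sglt1 inhibition constants, nM
#' @return list: per-segment `glucose_conc` (mmol/L), `reabsorbed`
#'   (mmol/h), `flux_in` (mmol/h), `uge_rate` (mmol/h), `filtered`
#'   (mmol/h)
#' @export
glucose_reabsorption <- function(subject, params, inhibitor = c(0, 0, 0),
                                 ki_sglt2 = 1, ki_sglt1 = 1) {
  inhibitor <- rep_len(inhibitor, 3)
  if (any(inhibitor < 0)) stop("negative inhibitor concentration")
  flows <- subject$tubule_flows                       # L/h at segment entry
  filtered <- subject$gfr_l_h * subject$plasma_glucose  # mmol/h
  vmax <- c(params$vmax_sglt2 / 2, params$vmax_sglt2 / 2, params$vmax_sglt1)
  km   <- c(params$km_sglt2, params$km_sglt2, params$km_sglt1)
  ki   <- c(ki_sglt2, ki_sglt2, ki_sglt1)

  flux_in <- numeric(3); reab <- numeric(3); s_conc <- numeric(3)
  fin <- filtered
  for (i in 1:3) {
    flux_in[i] <- fin
    s <- fin / flows[i]
    s_conc[i] <- s
    r <- inhibited_rate(vmax[i], km[i], s, inhibitor[i], ki[i])
    r <- min(r, fin)
    reab[i] <- r
    fin <- fin - r
  }
  names(flux_in) <- names(reab) <- names(s_conc) <- c("S1", "S2", "S3")
  list(glucose_conc = s_conc, reabsorbed = reab, flux_in = flux_in,
       uge_rate = fin, filtered = filtered)
}
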