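#' @title Tissue-to-plasma partitioning (Rodgers-Rowland, neutral species)
#' @name partition
#' @description Mechanistic tissue:plasma partition coefficients from the
#'   published neutral-species equations, using tissue water / neutral
#'   lipid / neutral phospholipid fractions and tissue:plasma albumin
#'   ratios pinned in `tissue_composition.csv`. The gliflozins carry no
#'   ionizable group of consequence at physiological pH, so the neutral
#'   form of the equations applies throughout.
NULL

#' Compute tissue partition coefficients and steady-state volume
#'
#' For each tissue, the unbound partition coefficient is
#' \deqn{Kpu = f_{EW} + f_{IW} + P f_{NL} + (0.3P + 0.7) f_{NPL} +
#'       \left(\frac{1}{fup} - 1 - P f_{NL,p} - (0.3P+0.7) f_{NPL,p}\right) RA}
#' with \eqn{P = 10^{logP}} (for adipose the vegetable-oil partition
#' \eqn{\log P_{vo} = 1.115\,logP - 1.35} replaces \eqn{logP}, the standard
#' correction for neutral lipid of adipose), and \eqn{Kp = fup \times Kpu}.
#' RA is the tissue:plasma albumin ratio carrying extracellular protein
#' binding. Vss is the plasma volume plus the Kp-weighted tissue volumes,
#' per kilogram of body weight.
#'
#' @param compound a [load_compound()] record
#' @param subject a [reference_subject()] physiology
#' @param kp_scale optional global multiplier on all Kp values (used by the
#'   distribution calibration; default 1 = pure bottom-up prediction)
#' @return object of class `partition_set`: `kp` (named vector), `vss`
#'   (L/kg), `method_tag`
#' @export
#' @examples
#' ps <- compute_kp(load_compound("ertugliflozin"), reference_subject())
#' ps$vss
compute_kp <- function(compound, subject, kp_scale = 1) {
  stopifnot(kp_scale > 0)
  comp <- .read_fixture("tissue_composition.csv")
  rownames(comp) <- comp$tissue
  tissues <- setdiff(.all_tissues, character(0))
  missing <- setdiff(tissues, comp$tissue)
  if (length(missing)) {
    stop("no tissue composition row for: ", paste(missing, collapse = ", "))
  }
  fup  <- compound$fup
  P    <- 10^compound$log_p
  Pvo  <- 10^(1.115 * compound$log_p - 1.35)
  pl   <- comp["plasma", ]
  plasma_lipid <- P * pl$f_nl + (0.3 * P + 0.7) * pl$f_npl
  prot_bracket <- 1 / fup - 1 - plasma_lipid
  kp <- vapply(tissues, function(t) {
    r  <- comp[t, ]
    Pt <- if (t == "adipose") Pvo else P
    kpu <- r$f_ew + r$f_iw + Pt * r$f_nl + (0.3 * Pt + 0.7) * r$f_npl +
      prot_bracket * r$ra_alb
    kpu * fup
  }, numeric(1))
  kp <- kp * kp_scale
  if (any(kp <= 0)) {
    stop("non-positive Kp computed (plasma lipid binding exceeds total ",
         "binding); check fup/logP inputs")
  }
  vols <- subject$tissue_volumes
  v_plasma <- vols["arterial"] + vols["venous"]
  vss <- (v_plasma + sum(vols[tissues] * kp[tissues])) / subject$body_weight
  structure(list(kp = kp, vss = unname(vss),
                 method_tag = "rodgers_single_neutral",
                 kp_scale = kp_scale),
            class = "partition_set")
}

#' Recompute Vss from a partition set (self-consistency check)
#'
#' @param partition a `partition_set`
#' @param subject the physiology it was computed for
#' @return Vss in L/kg
#' @export
vss_check <- function(partition, subject) {
  vols <- subject$tissue_volumes
  v_plasma <- vols["arterial"] + vols["venous"]
  tissues <- names(partition$kp)
  unname((v_plasma + sum(vols[tissues] * partition$kp)) /
           subject$body_weight)
}
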