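#' @title Competitive SGLT inhibition algebra and time courses
#' @name inhibition
#' @description The Michaelis-Menten rate, its competitively inhibited
#'   form, the Cheng-Prusoff conversion of IC50 to Ki, and the inhibition
#'   ratio `(1 - Vi/V0) x 100` evaluated along simulated concentration
#'   time courses at the duodenum, jejunum I, and proximal-tubule sites.
NULL

#' Cheng-Prusoff inhibition constant from an IC50 assay
#'
#' `Ki = IC50 / (1 + S'/Km')` for a competitive inhibitor, where S' is the
#' substrate concentration at which the IC50 was determined and Km' the
#' transporter's Michaelis constant in that assay.
#'
#' @param ic50 half-maximal inhibitory concentration, nM
#' @param s_assay substrate concentration in the assay, mmol/L
#' @param km_assay Michaelis constant in the assay, mmol/L
#' @return Ki in nM
#' @export
ki_from_ic50 <- function(ic50, s_assay, km_assay) {
  stopifnot(ic50 > 0, s_assay >= 0)
  if (!(km_assay > 0)) stop("km_assay must be positive")
  ic50 / (1 + s_assay / km_assay)
}

#' Michaelis-Menten rate
#' @param vmax maximal rate
#' @param km Michaelis constant, mmol/L
#' @param s substrate concentration, mmol/L
#' @return rate in the units of `vmax`
#' @export
mm_rate <- function(vmax, km, s) {
  stopifnot(km > 0, all(s >= 0))
  vmax * s / (km + s)
}

#' Competitively inhibited Michaelis-Menten rate
#' @inheritParams mm_rate
#' @param i inhibitor concentration, nM
#' @param ki inhibition constant, nM
#' @export
inhibited_rate <- function(vmax, km, s, i, ki) {
  stopifnot(km > 0, all(s >= 0), all(i >= 0))
  if (!(ki > 0)) stop("ki must be positive")
  vmax * s / (km * (1 + i / ki) + s)
}

#' Inhibition ratio of a competitive inhibitor
#'
#' `(1 - Vi/V0) * 100 = (1 - (Km+S) / (Km(1+I/Ki)+S)) * 100`; Vmax cancels
#' and is not required. At `s = 0` with `i = 0` the ratio is defined as 0
#' (the limit of Vi/V0 as S tends to 0 from above).
#'
#' @inheritParams inhibited_rate
#' @return percent inhibition, 0-100 (vectorized over `s` and `i`)
#' @export
inhibition_ratio <- function(km, s, i, ki) {
  stopifnot(km > 0, all(s >= 0), all(i >= 0))
  if (!(ki > 0)) stop("ki must be positive")
  (1 - (km + s) / (km * (1 + i / ki) + s)) * 100
}

.inhibition_sites <- c("duodenum", "jejunum1", "S1S2", "S3")

#' Concentration in nM from mg/mL
#' @noRd
.mg_ml_to_nm <- function(x, mw) x / mw * 1e9

#' Inhibition-ratio time course at one site
#'
#' For the gut sites (duodenum, jejunum I) the inhibitor is the dissolved
#' luminal drug concentration (only dissolved drug engages the apical
#' transporter; solubility caps it through the dissolution model),
#' converted to nM via the molecular weight, and the substrate is the
#' luminal glucose concentration. For the kidney sites the inhibitor is
#' the luminal filtrate concentration in the segment (S1S2 is reported at
#' the S2 flow, the distal end of the SGLT2-expressing region) and the
#' substrate is the segment glucose concentration from the reabsorption
#' cascade evaluated at each time point.
#'
#' SGLT2 is expressed only in the kidney S1/S2 segments, SGLT1 in the gut
#' and in S3; a site/transporter combination outside that map is an error.
#'
#' @param result a `sim_result`
#' @param site one of `"duodenum"`, `"jejunum1"`, `"S1S2"`, `"S3"`
#' @param transporter `"SGLT1"` or `"SGLT2"`
#' @param glucose [glucose_params()] for the kidney sites
#' @param luminal_glucose gut luminal glucose concentration, mmol/L
#'   (source-table value 1670, configurable)
#' @return object of class `inhibition_profile`: time (h), inhibitor_nM,
#'   substrate_mM, ratio (%), max_ratio, time_of_max
#' @export
inhibition_timecourse <- function(result, site, transporter,
                                  glucose = glucose_params(),
                                  luminal_glucose = 1670) {
  stopifnot(inherits(result, "sim_result"))
  site <- match.arg(site, .inhibition_sites)
  transporter <- match.arg(toupper(transporter), c("SGLT1", "SGLT2"))
  ok <- (site %in% c("duodenum", "jejunum1") && transporter == "SGLT1") ||
        (site == "S1S2" && transporter == "SGLT2") ||
        (site == "S3" && transporter == "SGLT1")
  if (!ok) {
    stop(transporter, " is not modeled at site '", site,
         "' (SGLT1: duodenum, jejunum1, S3; SGLT2: S1S2)")
  }
  cpd <- result$spec$compound
  sub <- result$spec$subject
  tt <- result$time

  if (site %in% c("duodenum", "jejunum1")) {
    i_nm <- .mg_ml_to_nm(result$luminal_dissolved[, site], cpd$molecular_weight)
    s <- rep_len(luminal_glucose, length(tt))
    km <- glucose$km_sglt1
    ki <- cpd$ki_sglt1
    ratio <- inhibition_ratio(km, s, i_nm, ki)
  } else {
    # per-time-point cascade: segment glucose depends on upstream inhibition
    conc <- result$tubule_drug                      # ng/mL filtrate
    i_seg_nm <- conc / cpd$molecular_weight * 1000  # ng/mL -> nM
    n <- length(tt)
    s <- numeric(n); i_nm <- numeric(n); ratio <- numeric(n)
    col <- if (site == "S1S2") "S2" else "S3"
    km <- if (site == "S1S2") glucose$km_sglt2 else glucose$km_sglt1
    ki <- if (site == "S1S2") cpd$ki_sglt2 else cpd$ki_sglt1
    for (k in seq_len(n)) {
      casc <- glucose_reabsorption(sub, glucose, inhibitor = i_seg_nm[k, ],
                                   ki_sglt2 = cpd$ki_sglt2,
                                   ki_sglt1 = cpd$ki_sglt1)
      s[k] <- casc$glucose_conc[[col]]
      i_nm[k] <- i_seg_nm[k, col]
      ratio[k] <- inhibition_ratio(km, s[k], i_nm[k], ki)
    }
  }
  imax <- which.max(ratio)
  structure(list(site = site, transporter = transporter,
                 compound = cpd$name,
                 dose_mg = result$spec$regimen$dose_mg,
                 time = tt, inhibitor_nM = i_nm, substrate_mM = s,
                 ratio = ratio,
                 max_ratio = ratio[imax], time_of_max = tt[imax]),
            class = "inhibition_profile")
}

#' @export
print.inhibition_profile <- function(x, ...) {
  cat(sprintf("<inhibition_profile> %s %.4g mg, %s at %s\n", x$compound,
              x$dose_mg, x$transporter, x$site))
  cat(sprintf("  max ratio %.4g%% at %.2f h\n", x$max_ratio, x$time_of_max))
  invisible(x)
}

#' Ratio at a given time (linear interpolation on the stored grid)
#' @param profile an `inhibition_profile`
#' @param t_h time, h
#' @return percent inhibition
#' @export
ratio_at <- function(profile, t_h) {
  approx(profile$time, profile$ratio, xout = t_h)$y
}

#' Maximum-inhibition summary across sites for one simulation
#'
#' @param result a `sim_result`
#' @inheritParams inhibition_timecourse
#' @return data.frame: site, transporter, max_ratio_pct, time_of_max_h
#' @export
inhibition_summary <- function(result, glucose = glucose_params(),
                               luminal_glucose = 1670) {
  combos <- data.frame(
    site = .inhibition_sites,
    transporter = c("SGLT1", "SGLT1", "SGLT2", "SGLT1"))
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    p <- inhibition_timecourse(result, combos$site[k], combos$transporter[k],
                               glucose = glucose,
                               luminal_glucose = luminal_glucose)
    data.frame(site = p$site, transporter = p$transporter,
               compound = p$compound, dose_mg = p$dose_mg,
               max_ratio_pct = p$max_ratio, time_of_max_h = p$time_of_max)
  })
  do.call(rbind, rows)
}
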