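#' @title Whole-body perfusion-limited PBPK model
#' @name pbpk
#' @description Assembles the 14-compartment perfusion-limited ODE system
#'   (lung in series between venous and arterial blood; spleen and gut
#'   tissue draining portally into the liver) coupled to the nine
#'   ACAT gut compartments, and integrates it with a stiff-capable
#'   adaptive solver.
#'
#'   Convention: all compartment states are drug amounts (mg).
#'   Concentrations are plasma-referenced; the tissue-exit plasma
#'   concentration is `C_t * Rbp / Kp_t`, so that at steady state
#'   `C_t = Kp_t * C_arterial / Rbp`. Hepatic elimination acts on the
#'   liver-exit plasma concentration with the total hepatic clearance
#'   capped at hepatic plasma flow (well-stirred sanity cap); renal
#'   elimination is filtration only, `GFR * fup * C_arterial`, routed to
#'   the urine accumulator.
NULL

# state vector layout (names used for dosing events, integers in the RHS)
.state_template <- function() {
  c(setNames(numeric(9), paste0("u_", .gut_compartments)),
    setNames(numeric(9), paste0("d_", .gut_compartments)),
    cum_fecal = 0, cum_absorbed = 0, cum_gut_extracted = 0,
    setNames(numeric(12), paste0("A_", c(.venous_tissues, .portal_tissues,
                                         "liver", "lung"))),
    A_arterial = 0, A_venous = 0,
    cum_urine = 0, cum_hepatic = 0)
}

#' Assemble a full model specification
#'
#' @param compound `compound_record` (possibly with overridden fields)
#' @param subject `subject_physiology`
#' @param partition `partition_set` from [compute_kp()]
#' @param absorption `absorption_settings` from [default_absorption()]
#' @param regimen `dose_regimen`
#' @param solver list with `rtol`, `atol`, `grid` (output times, h)
#' @return object of class `model_spec`
#' @export
model_spec <- function(compound, subject, partition, absorption, regimen,
                       solver = NULL) {
  validate_subject(subject)
  if (is.null(solver)) solver <- list()
  horizon <- if (regimen$n_doses > 1) {
    (regimen$n_doses - 1) * regimen$interval_h + 72
  } else 72
  solver <- modifyList(list(rtol = 1e-8, atol = 1e-10,
                            grid = seq(0, horizon, by = 0.05)), solver)
  stopifnot(solver$rtol > 0, solver$atol > 0,
            all(diff(solver$grid) > 0), solver$grid[1] == 0)
  structure(list(compound = compound, subject = subject,
                 partition = partition, absorption = absorption,
                 regimen = regimen, solver = solver),
            class = "model_spec")
}

# shared constants of the assembled ODE system; also the source of the
# parameter vector handed to the compiled right-hand side
.model_constants <- function(spec) {
  sub <- spec$subject
  validate_subject(sub)
  cpd <- spec$compound
  abs <- spec$absorption
  kp  <- spec$partition$kp
  bw  <- spec$regimen$body_weight_kg

  vols <- sub$tissue_volumes
  q    <- sub$plasma_flows
  co   <- sub$cardiac_output
  qh   <- unname(q["liver"] + sum(q[.portal_tissues]))
  tiss_order <- c(.venous_tissues, .portal_tissues, "liver", "lung")
  list(
    tiss_order = tiss_order,
    v_t = unname(vols[tiss_order]),
    q_t = unname(q[tiss_order]),
    exit_k = unname(cpd$rbp / kp[tiss_order]),
    co = co, qh = qh, q_ha = unname(q["liver"]),
    cl_hep = min(cpd$cl_hepatic * bw, qh),       # L/h, well-stirred cap
    cl_ren_u = sub$gfr_l_h * cpd$fup,            # L/h on arterial plasma
    v_art = unname(vols["arterial"]), v_ven = unname(vols["venous"]),
    kt = unname(1 / abs$transit_h),
    gvol = unname(abs$luminal_volume_ml),
    cs = cpd$solubility, kdiss = abs$dissolution_k,
    pa = unname(cpd$peff * abs$asf),
    gfrac = abs$fraction_gut_extracted)
}

.ode_parms <- function(spec) {
  k <- .model_constants(spec)
  c(k$kt, k$gvol, k$cs, k$kdiss, k$pa, k$gfrac, k$v_t, k$q_t, k$exit_k,
    k$co, k$qh, k$q_ha, k$cl_hep, k$cl_ren_u, k$v_art, k$v_ven)
}

#' Build the ODE right-hand side for a model specification
#'
#' Returns `function(t, y, parms)` in deSolve form over the full state
#' vector (gut lumen, 12 tissues, arterial and venous blood, cumulative
#' fecal/absorbed/extracted/urine/hepatic accumulators). The subject's
#' venous-return flow balance is checked before the function is built.
#' This is the reference (pure-R) implementation; [simulate_pbpk()] uses
#' a compiled translation of the same equations, and the two are held to
#' agreement in the test suite.
#'
#' @param spec a [model_spec()]
#' @return deSolve-compatible derivative function
#' @export
build_ode <- function(spec) {
  k <- .model_constants(spec)
  # integer state indices
  iu <- 1:9; id <- 10:18; ifec <- 19L; iabs <- 20L; iext <- 21L
  tiss_order <- k$tiss_order
  it <- 22:33; names(it) <- tiss_order
  iart <- 34L; iven <- 35L; iur <- 36L; ihep <- 37L

  v_t <- k$v_t; q_t <- k$q_t; co <- k$co; qh <- k$qh; q_ha <- k$q_ha
  cl_hep <- k$cl_hep; cl_ren_u <- k$cl_ren_u
  v_art <- k$v_art; v_ven <- k$v_ven
  i_ven_t <- seq_along(.venous_tissues)
  i_spleen <- which(tiss_order == "spleen")
  i_gut    <- which(tiss_order == "gut")
  i_liver  <- which(tiss_order == "liver")
  i_lung   <- which(tiss_order == "lung")

  # exit plasma concentration coefficient per tissue: Ct * rbp / kp
  exit_k <- k$exit_k
  i_not_lung <- which(tiss_order != "lung")
  q_sys <- sum(q_t[i_not_lung])                  # equals cardiac output
  q_spl <- q_t[i_spleen]; q_gut <- q_t[i_gut]
  q_nl <- q_t[i_not_lung]; exit_nl <- exit_k[i_not_lung]

  # gut constants (the same arithmetic as gut_derivs, inlined and
  # precomputed for the solver's inner loop)
  kt <- k$kt; gvol <- k$gvol; cs <- k$cs; kdiss <- k$kdiss
  pa <- k$pa; gfrac <- k$gfrac

  function(t, y, parms) {
    u <- y[iu]; d <- y[id]
    tr_u <- kt * u; tr_d <- kt * d
    diss <- kdiss * u * (cs - d / gvol)
    abs_flux <- pa * d
    absorbed_rate <- sum(abs_flux)
    portal_rate <- (1 - gfrac) * absorbed_rate

    c_exit <- (y[it] / v_t) * exit_k             # plasma-referenced exit conc
    ca <- y[iart] / v_art
    cv <- y[iven] / v_ven

    d_t <- numeric(12)
    d_t[i_not_lung] <- q_nl * ca - q_nl * c_exit[i_not_lung]
    d_t[i_lung] <- co * (cv - c_exit[i_lung])
    # liver: hepatic artery + portal streams + absorbed drug, minus
    # hepatic-vein outflow and hepatic elimination
    d_t[i_liver] <- q_ha * ca +
      q_spl * c_exit[i_spleen] + q_gut * c_exit[i_gut] +
      portal_rate - (qh + cl_hep) * c_exit[i_liver]
    # spleen and gut tissue exit into the liver, not the venous pool
    dy <- numeric(37)
    dy[iu] <- c(0, tr_u[-9L]) - tr_u - diss
    dy[id] <- c(0, tr_d[-9L]) - tr_d + diss - abs_flux
    dy[ifec] <- tr_u[9L] + tr_d[9L]
    dy[iabs] <- absorbed_rate
    dy[iext] <- gfrac * absorbed_rate
    dy[it] <- d_t
    dy[iart] <- co * c_exit[i_lung] - q_sys * ca - cl_ren_u * ca
    dy[iven] <- sum(q_t[i_ven_t] * c_exit[i_ven_t]) +
      qh * c_exit[i_liver] - co * cv
    dy[iur] <- cl_ren_u * ca
    dy[ihep] <- cl_hep * c_exit[i_liver]
    list(dy)
  }
}

#' Simulate a dosing regimen
#'
#' Integrates the full system with `deSolve::lsoda`. Multiple doses are
#' dosing events that add drug to the stomach at `k * interval_h`; no
#' superposition is used. The default first dose is undissolved solid in
#' the stomach; `dose_to` exists as a numerical-validation hook (dosing
#' the dissolved pool keeps the whole system linear, dosing the venous
#' compartment reduces it to closed-form kinetics for solver checks).
#'
#' @param spec a [model_spec()]
#' @param dose_to where the dose is placed: `"stomach_solid"` (default),
#'   `"stomach_solution"`, or `"venous"` (verification hook)
#' @return object of class `sim_result`; see Details
#' @details The result carries the output time grid (h), venous plasma
#'   concentration (ng/mL), per-tissue concentrations (ng/mL), luminal
#'   dissolved concentrations (mg/mL), proximal-tubule segment drug
#'   concentrations (ng/mL, filtrate convention), cumulative urinary /
#'   hepatic / fecal / gut-extracted amounts (mg) and the worst global
#'   mass-balance residual as a fraction of the administered dose.
#' @param engine `"compiled"` (C translation of the equations, default)
#'   or `"r"` (the [build_ode()] reference implementation)
#' @export
simulate_pbpk <- function(spec, dose_to = c("stomach_solid",
                                            "stomach_solution", "venous"),
                          engine = c("compiled", "r")) {
  dose_to <- match.arg(dose_to)
  engine <- match.arg(engine)
  reg <- spec$regimen
  y0 <- .state_template()
  slot <- switch(dose_to, stomach_solid = "u_stomach",
                 stomach_solution = "d_stomach", venous = "A_venous")
  y0[slot] <- reg$dose_mg

  times <- spec$solver$grid
  events <- NULL
  if (reg$n_doses > 1) {
    etimes <- reg$interval_h * seq_len(reg$n_doses - 1)
    events <- list(data = data.frame(
      var = which(names(y0) == slot), time = etimes, value = reg$dose_mg,
      method = "add"))
    times <- sort(unique(c(times, etimes)))
  }

  out <- if (engine == "compiled") {
    lsoda(y = y0, times = times, func = "sgltsim_derivs",
          dllname = "sgltsim", initfunc = "sgltsim_initmod",
          parms = .ode_parms(spec),
          rtol = spec$solver$rtol, atol = spec$solver$atol,
          events = events)
  } else {
    lsoda(y = y0, times = times, func = build_ode(spec), parms = NULL,
          rtol = spec$solver$rtol, atol = spec$solver$atol,
          events = events)
  }
  if (attr(out, "istate")[1] < 0) {
    stop("ODE solver failed (istate ", attr(out, "istate")[1],
         ") at t ~ ", max(out[, "time"]), " h; state norm ",
         format(sqrt(sum(out[nrow(out), -1]^2))))
  }
  out <- as.data.frame(out)

  sub <- spec$subject; cpd <- spec$compound
  v <- sub$tissue_volumes
  mg_l_to_ng_ml <- 1000
  # clip solver undershoot (O(atol) negative excursions) in the reported
  # concentrations; the raw trajectories used for mass balance are kept
  plasma <- pmax(out$A_venous / v[["venous"]] * mg_l_to_ng_ml, 0)
  arterial <- pmax(out$A_arterial / v[["arterial"]] * mg_l_to_ng_ml, 0)
  tiss <- sapply(c(.venous_tissues, .portal_tissues, "liver", "lung"),
                 function(t) pmax(out[[paste0("A_", t)]] / v[[t]] *
                                    mg_l_to_ng_ml, 0))
  lum <- sapply(.gut_compartments, function(g)
    pmax(out[[paste0("d_", g)]] / spec$absorption$luminal_volume_ml[[g]],
         0))

  # quasi-steady tubule drug concentrations (filtrate convention)
  frac <- sub$tubule_flow_fractions
  tub <- outer(arterial * cpd$fup, 1 / frac)
  colnames(tub) <- names(frac)

  body_amt <- rowSums(out[, paste0("A_", c(.venous_tissues, .portal_tissues,
                                           "liver", "lung"))]) +
    out$A_arterial + out$A_venous
  lumen_amt <- rowSums(out[, paste0("u_", .gut_compartments)]) +
    rowSums(out[, paste0("d_", .gut_compartments)])
  dosed <- reg$dose_mg * (1 + findInterval(out$time - 1e-9,
             reg$interval_h * seq_len(reg$n_doses - 1)))
  if (reg$n_doses == 1) dosed <- rep(reg$dose_mg, nrow(out))
  balance <- dosed - (body_amt + lumen_amt + out$cum_fecal +
                        out$cum_gut_extracted + out$cum_urine +
                        out$cum_hepatic)
  residual <- if (reg$dose_mg > 0) {
    max(abs(balance)) / (reg$dose_mg * reg$n_doses)
  } else max(abs(balance))

  structure(list(
    time = out$time,
    plasma_concentration = plasma,         # ng/mL, venous
    arterial_concentration = arterial,     # ng/mL
    tissue_concentration = tiss,           # ng/mL
    luminal_dissolved = lum,               # mg/mL
    tubule_drug = tub,                     # ng/mL filtrate
    cumulative_urinary_excretion = out$cum_urine,       # mg
    cumulative_hepatic_elimination = out$cum_hepatic,   # mg
    cumulative_fecal = out$cum_fecal,
    cumulative_absorbed = out$cum_absorbed,
    cumulative_gut_extracted = out$cum_gut_extracted,
    mass_balance_residual = residual,
    raw = out, spec = spec
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %s %.4g mg x %d\n", x$spec$compound$name,
              x$spec$regimen$dose_mg, x$spec$regimen$n_doses))
  cat(sprintf("  grid 0-%.5g h (%d points); Cmax %.4g ng/mL\n",
              max(x$time), length(x$time), max(x$plasma_concentration)))
  cat(sprintf("  urinary %.4g mg, hepatic %.4g mg, mass-balance residual %.2e\n",
              max(x$cumulative_urinary_excretion),
              max(x$cumulative_hepatic_elimination),
              x$mass_balance_residual))
  invisible(x)
}

#' High-level model builder for one compound and dose
#'
#' Convenience wrapper assembling compound record, reference subject,
#' partitioning, absorption settings and regimen into a [model_spec()].
#' `params` accepts calibration overrides: compound-level `peff`
#' (1e-4 cm/s), `rbp`, `log_p`, `solubility` (mg/mL); absorption-level
#' `asf_coefficient`, `stomach_transit_h`, `small_intestine_transit_h`,
#' `colon_transit_h`, `fraction_gut_extracted`, `dissolution_k`; and
#' distribution-level `kp_scale`.
#'
#' @param compound name or `compound_record`
#' @param dose_mg dose per administration (mg)
#' @param n_doses,interval_h regimen; defaults to a single dose
#' @param subject physiology (default [reference_subject()])
#' @param params named list of overrides (see above)
#' @param solver optional solver settings passed to [model_spec()]
#' @return a `model_spec`
#' @export
build_model <- function(compound, dose_mg, n_doses = 1L, interval_h = 24,
                        subject = reference_subject(), params = list(),
                        solver = NULL) {
  cpd <- if (inherits(compound, "compound_record")) compound
         else load_compound(compound)
  for (f in intersect(names(params), c("rbp", "log_p", "solubility"))) {
    cpd[[f]] <- params[[f]]
  }
  if ("peff" %in% names(params)) {          # given on the 1e-4 cm/s scale
    cpd$peff_1e4_cm_s <- params$peff
    cpd$peff <- params$peff * 1e-4 * 3600
  }
  validate_compound(cpd)
  kp_scale <- if ("kp_scale" %in% names(params)) params$kp_scale else 1
  part <- compute_kp(cpd, subject, kp_scale = kp_scale)
  abs_args <- params[intersect(names(params),
    c("asf_coefficient", "stomach_transit_h", "small_intestine_transit_h",
      "colon_transit_h", "fraction_gut_extracted", "dissolution_k",
      "colon_factor"))]
  absn <- do.call(default_absorption,
                  c(list(compound = cpd, subject = subject), abs_args))
  reg <- dose_regimen(dose_mg, n_doses = n_doses, interval_h = interval_h,
                      body_weight_kg = subject$body_weight)
  model_spec(cpd, subject, part, absn, reg, solver = solver)
}
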