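test_that("compiled and reference R right-hand sides agree", {
  spec <- build_model("henagliflozin", 2.5,
                      solver = list(rtol = 1e-8, atol = 1e-10,
                                    grid = seq(0, 48, by = 0.25)))
  rc <- simulate_pbpk(spec, engine = "compiled")
  rr <- simulate_pbpk(spec, engine = "r")
  expect_lt(max(abs(rc$plasma_concentration - rr$plasma_concentration) /
                  (abs(rr$plasma_concentration) + 1e-9)), 1e-6)
  expect_lt(max(abs(rc$cumulative_urinary_excretion -
                      rr$cumulative_urinary_excretion)), 1e-9)
})

test_that("a zero dose yields all-zero trajectories", {
  spec <- build_model("ertugliflozin", 0,
                      solver = list(grid = seq(0, 24, by = 1)))
  res <- simulate_pbpk(spec)
  expect_equal(max(abs(res$plasma_concentration)), 0)
  expect_equal(max(res$cumulative_urinary_excretion), 0)
})

test_that("the degenerate configuration reproduces one-compartment
           closed-form kinetics", {
  # all tissues shrunk to negligible volume, Kp = Rbp = 1, no hepatic
  # clearance, and a near-infinite cardiac output collapse the system to
  # a single well-mixed plasma pool eliminated by renal filtration:
  # C(t) = (D/V) exp(-CL t / V)
  sub <- reference_subject(cardiac_output_plasma_l_h = 1e7)
  tiny <- c("heart", "brain", "muscle", "adipose", "skin", "bone_rest",
            "kidney", "reproductive", "spleen", "gut", "liver", "lung")
  sub$tissue_volumes[tiny] <- 1e-9
  cpd <- load_compound("ertugliflozin")
  cpd$rbp <- 1
  cpd$cl_hepatic <- 0
  spec <- build_model(cpd, 10, subject = sub,
                      solver = list(rtol = 1e-11, atol = 1e-13,
                                    grid = seq(0, 24, by = 0.5)))
  spec$partition$kp[] <- 1
  res <- simulate_pbpk(spec, dose_to = "venous")
  v <- sum(sub$tissue_volumes[c("arterial", "venous")]) + 12e-9
  cl <- sub$gfr_l_h * cpd$fup
  keep <- res$time >= 0.5              # past the fast mixing transient
  analytic <- 10 / v * exp(-cl * res$time[keep] / v) * 1000  # ng/mL
  expect_lt(max(abs(res$plasma_concentration[keep] - analytic) /
                  analytic), 1e-6)
})

test_that("exposure is dose-linear and obeys superposition", {
  auc_solution <- function(key, dose, n_doses = 1) {
    r <- cached(key, {
      spec <- build_model("ertugliflozin", dose, n_doses = n_doses,
                          interval_h = 12,
                          solver = list(rtol = 1e-9, atol = 1e-11,
                                        grid = seq(0, 240, by = 0.25)))
      simulate_pbpk(spec, dose_to = "stomach_solution")
    })
    nca_sim(r)$auc_0_t
  }
  a1 <- auc_solution("lin_1", 1)
  a2 <- auc_solution("lin_2", 2)
  expect_equal(a2 / a1, 2, tolerance = 1e-3)
  # two half doses 12 h apart carry the same total exposure
  a_split <- auc_solution("lin_split", 0.5, n_doses = 2)
  expect_equal(a_split / a1, 1, tolerance = 1e-4)
})

test_that("once-daily sotagliflozin reaches a periodic steady state by
           day 8", {
  res <- cached("sota_qd8", {
    spec <- build_model("sotagliflozin", 200, n_doses = 8,
                        interval_h = 24,
                        params = test_calibration("sotagliflozin"),
                        solver = list(rtol = 1e-8, atol = 1e-10,
                                      grid = seq(0, 216, by = 0.1)))
    simulate_pbpk(spec)
  })
  auc_day <- function(day) {
    sel <- res$time >= (day - 1) * 24 & res$time <= day * 24
    t <- res$time[sel]; c <- res$plasma_concentration[sel]
    sum(diff(t) * (head(c, -1) + c[-1]) / 2)
  }
  expect_lt(abs(auc_day(8) - auc_day(7)) / auc_day(7), 0.01)
})

test_that("halving the solver tolerances leaves the exposure unchanged", {
  spec1 <- build_model("empagliflozin", 10,
                       solver = list(rtol = 1e-6, atol = 1e-9,
                                     grid = seq(0, 72, by = 0.1)))
  spec2 <- build_model("empagliflozin", 10,
                       solver = list(rtol = 5e-7, atol = 5e-10,
                                     grid = seq(0, 72, by = 0.1)))
  a1 <- nca_sim(simulate_pbpk(spec1))$auc_0_t
  a2 <- nca_sim(simulate_pbpk(spec2))$auc_0_t
  expect_lt(abs(a1 - a2) / a2, 1e-3)
})

test_that("global mass balance closes on oral and multiple dosing", {
  r1 <- test_sim("mb_single", "henagliflozin", 10)
  expect_lt(r1$mass_balance_residual, 1e-6)
  r2 <- cached("sota_qd8", {
    spec <- build_model("sotagliflozin", 200, n_doses = 8,
                        interval_h = 24,
                        params = test_calibration("sotagliflozin"),
                        solver = list(rtol = 1e-8, atol = 1e-10,
                                      grid = seq(0, 216, by = 0.1)))
    simulate_pbpk(spec)
  })
  expect_lt(r2$mass_balance_residual, 1e-6)
})

test_that("urinary fraction follows the filtration/hepatic split
           (well-stirred form)", {
  res <- cached("uf_ertu", {
    spec <- build_model("ertugliflozin", 1,
                        solver = list(rtol = 1e-9, atol = 1e-11,
                                      grid = seq(0, 400, by = 0.5)))
    simulate_pbpk(spec)
  })
  sub <- res$spec$subject; cpd <- res$spec$compound
  q <- sub$plasma_flows
  qh <- unname(q["liver"] + q["spleen"] + q["gut"])
  clh <- cpd$cl_hepatic * 70
  clr <- sub$gfr_l_h * cpd$fup
  fh <- qh / (qh + clh)                 # hepatic first-pass availability
  clh_eff <- clh * fh                   # systemic hepatic clearance
  n <- length(res$time)
  portal <- res$cumulative_absorbed[n] - res$cumulative_gut_extracted[n]
  observed <- res$cumulative_urinary_excretion[n] / portal
  analytic <- fh * clr / (clr + clh_eff)
  expect_lt(abs(observed - analytic) / analytic, 0.01)
})

test_that("flow-imbalanced subjects are rejected before integration", {
  sub <- reference_subject()
  sub$plasma_flows["muscle"] <- sub$plasma_flows["muscle"] * 2
  expect_error(build_model("ertugliflozin", 1, subject = sub),
               "venous return")
})
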