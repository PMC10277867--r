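test_that("filtrate drug concentrations follow GFR x fup and water
           reabsorption", {
  sub <- reference_subject()
  cpd <- load_compound("sotagliflozin")
  tc <- tubule_concentrations(c(0, 100), cpd, sub)
  expect_equal(unname(tc[1, ]), c(0, 0, 0))
  # S1 carries the full filtrate flow, so its concentration is fup * Cp
  expect_equal(unname(tc[2, "S1"]), 100 * cpd$fup)
  # S3 flow = 0.4 GFR concentrates the filtrate 2.5-fold
  expect_equal(unname(tc[2, "S3"]), 2.5 * 100 * cpd$fup)

  # no water reabsorption: every segment sees fup * Cp
  sub2 <- reference_subject(tubule_flow_fractions = c(S1 = 1, S2 = 1,
                                                      S3 = 1))
  tc2 <- tubule_concentrations(100, cpd, sub2)
  expect_equal(unname(tc2[1, ]), rep(100 * cpd$fup, 3))
})

test_that("glucose is conserved through the reabsorption cascade", {
  sub <- reference_subject()
  gp <- glucose_params()
  for (i_nm in list(c(0, 0, 0), c(50, 80, 200), c(1e5, 1e5, 1e5))) {
    casc <- glucose_reabsorption(sub, gp, inhibitor = i_nm,
                                 ki_sglt2 = 1.41, ki_sglt1 = 7.02)
    closure <- casc$filtered - sum(casc$reabsorbed) - casc$uge_rate
    expect_lt(abs(closure) / casc$filtered, 1e-9)
    expect_true(all(casc$reabsorbed >= 0))
    expect_true(casc$uge_rate >= 0)
  }
})

test_that("without inhibitor the filtered load is fully reabsorbed", {
  casc <- glucose_reabsorption(reference_subject(), glucose_params())
  # filtered load (GFR x 5 mmol/L ~ 40 mmol/h) is far below the combined
  # transport maximum, so urinary glucose is essentially nil
  expect_lt(casc$uge_rate / casc$filtered, 1e-6)
})

test_that("SGLT2 blockade pushes glucose into S3 and raises UGE", {
  sub <- reference_subject()
  gp <- glucose_params()
  base <- glucose_reabsorption(sub, gp, inhibitor = c(0, 0, 0),
                               ki_sglt2 = 1, ki_sglt1 = 1)
  # inhibitor present only in S1/S2, 99% SGLT2 inhibition territory
  blocked <- glucose_reabsorption(sub, gp, inhibitor = c(1e4, 1e4, 0),
                                  ki_sglt2 = 1, ki_sglt1 = 1)
  expect_gt(blocked$flux_in[["S3"]], base$flux_in[["S3"]])
  expect_gt(blocked$uge_rate, base$uge_rate)
})

test_that("UGE rises monotonically with inhibitor concentration", {
  sub <- reference_subject()
  gp <- glucose_params()
  uge <- vapply(c(0, 1, 10, 100, 1000, 1e4, 1e5), function(i) {
    glucose_reabsorption(sub, gp, inhibitor = rep(i, 3),
                         ki_sglt2 = 1.41, ki_sglt1 = 7.02)$uge_rate
  }, numeric(1))
  expect_true(all(diff(uge) >= 0))
})

test_that("unbounded transport capacity removes all luminal glucose", {
  gp <- glucose_params(vmax_sglt2 = 1e9, vmax_sglt1 = 1e9)
  casc <- glucose_reabsorption(reference_subject(), gp)
  expect_equal(casc$uge_rate, 0, tolerance = 1e-6)
})

test_that("negative inhibitor concentrations are rejected", {
  expect_error(glucose_reabsorption(reference_subject(), glucose_params(),
                                    inhibitor = c(-1, 0, 0)),
               "negative")
})
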