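test_that("compound records carry the printed parameters, normalized", {
  ert <- load_compound("ertugliflozin")
  expect_equal(ert$fup, 0.064)
  expect_equal(ert$rbp, 0.66)
  expect_equal(ert$ki_sglt2, 0.88)
  # case-insensitive lookup
  expect_equal(load_compound("Sotagliflozin")$ki_sglt1, 7.02)
  expect_equal(load_compound("SOTAGLIFLOZIN")$ki_sglt2, 1.41)
  # permeability normalized from the 1e-4 cm/s print scale to cm/h
  expect_equal(ert$peff, 4.1e-4 * 3600)
  # solubility unit tag resolves to mg/mL and denormalizes to the printed
  # number exactly
  expect_equal(ert$solubility, 0.163)
  expect_identical(ert$solubility_printed, 0.163)
})

test_that("every shipped compound passes its record invariants", {
  for (nm in c("ertugliflozin", "empagliflozin", "henagliflozin",
               "sotagliflozin")) {
    rec <- load_compound(nm)
    expect_true(rec$fup > 0 && rec$fup <= 1, info = nm)
    expect_true(rec$cl_hepatic <= rec$cl_total, info = nm)
    expect_true(all(c(rec$ki_sglt1, rec$ki_sglt2, rec$peff,
                      rec$solubility) > 0), info = nm)
  }
})

test_that("unknown compounds raise an error naming the available four", {
  expect_error(load_compound("dapagliflozin"), "ertugliflozin")
  expect_error(load_compound("dapagliflozin"), "sotagliflozin")
  expect_error(load_observed_pk("canagliflozin"), "available")
})

test_that("observed PK table has the printed doses and values", {
  hena <- load_observed_pk("henagliflozin")
  expect_equal(nrow(hena), 7)
  r25 <- hena[hena$dose_mg == 2.5, ]
  expect_equal(r25$auc, 408)
  expect_equal(r25$cmax, 54.8)
  expect_equal(r25$tmax, 1.5)

  sota <- load_observed_pk("sotagliflozin")
  expect_equal(nrow(sota), 2)
  expect_equal(sota$auc[sota$dose_mg == 200], 631.14)

  expect_equal(nrow(load_observed_pk("ertugliflozin")), 4)
  empa <- load_observed_pk("empagliflozin")
  expect_equal(nrow(empa), 4)
  expect_setequal(empa$dose_mg, c(1, 10, 25, 100))
})

test_that("fixtures round-trip through their CSV representation", {
  for (f in c("compounds.csv", "observed_pk.csv", "inhibition_max.csv",
              "physiology.csv", "tissue_composition.csv")) {
    tab <- sgltsim:::.read_fixture(f)
    tmp <- tempfile(fileext = ".csv")
    write.csv(tab, tmp, row.names = FALSE, quote = FALSE)
    back <- read.csv(tmp, stringsAsFactors = FALSE)
    expect_equal(back, tab, info = f)
    unlink(tmp)
  }
})

test_that("dose regimens validate their inputs", {
  expect_error(dose_regimen(-1), "dose_mg")
  expect_error(dose_regimen(10, n_doses = 3, interval_h = 0), "interval")
  reg <- dose_regimen(200, n_doses = 8, interval_h = 24)
  expect_equal(reg$n_doses, 8L)
})
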