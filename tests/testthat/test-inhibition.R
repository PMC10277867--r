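test_that("Cheng-Prusoff conversion and its round trip", {
  expect_equal(ki_from_ic50(10, 0, 0.4), 10)
  expect_equal(ki_from_ic50(10, 0.4, 0.4), 5)
  expect_error(ki_from_ic50(10, 1, 0), "km_assay")

  # round trip: with the returned Ki, the concentration halving the
  # competitive rate at S' equals the original IC50 (root-finding oracle)
  ic50 <- 37.5; s <- 1.2; km <- 0.4
  ki <- ki_from_ic50(ic50, s, km)
  v0 <- mm_rate(1, km, s)
  f <- function(i) inhibited_rate(1, km, s, i, ki) - v0 / 2
  i_half <- uniroot(f, c(1e-6, 1e6), tol = 1e-12)$root
  expect_lt(abs(i_half - ic50) / ic50, 1e-9)
})

test_that("Michaelis-Menten algebra is exact", {
  expect_equal(mm_rate(3, 2, 0), 0)
  expect_equal(mm_rate(3, 2, 2), 1.5)
  expect_equal(mm_rate(1, 2, 200), 0.990099, tolerance = 1e-6)

  expect_equal(inhibited_rate(3, 2, 5, 0, 1), mm_rate(3, 2, 5))
  expect_lt(inhibited_rate(3, 2, 5, 1e15, 1), 1e-12)
  expect_equal(inhibited_rate(3, 2, 2, 7, 7), 1, tolerance = 1e-9)  # vmax/3

  expect_equal(inhibition_ratio(2, 2, 0, 7), 0)
  expect_equal(inhibition_ratio(2, 2, 7, 7), 100 / 3, tolerance = 1e-9)
  # i/ki = 1000 with s << km approaches 1 - 1/1001
  expect_equal(inhibition_ratio(2, 2e-9, 1000, 1),
               100 * (1 - 1 / 1001), tolerance = 1e-6)
})

test_that("the inhibition ratio cancels Vmax and is monotone", {
  set.seed(11)
  for (rep in 1:50) {
    km <- runif(1, 0.1, 10); s <- runif(1, 0, 50)
    i <- runif(1, 0, 1e4); ki <- runif(1, 0.1, 100)
    vmax <- runif(1, 0.5, 500)
    direct <- inhibition_ratio(km, s, i, ki)
    via_rates <- 100 * (1 - inhibited_rate(vmax, km, s, i, ki) /
                          mm_rate(vmax, km, max(s, 1e-12)))
    expect_equal(direct, via_rates, tolerance = 1e-9)
  }
  # strictly increasing in I, decreasing in S
  i_grid <- seq(0, 1000, by = 50)
  r_i <- inhibition_ratio(2, 5, i_grid, 7)
  expect_true(all(diff(r_i) > 0))
  s_grid <- seq(0.1, 100, by = 5)
  r_s <- inhibition_ratio(2, s_grid, 100, 7)
  expect_true(all(diff(r_s) < 0))
})

test_that("site/transporter combinations outside the expression map fail", {
  res <- test_sim("inh_ertu5", "ertugliflozin", 5)
  expect_error(inhibition_timecourse(res, "duodenum", "SGLT2"),
               "not modeled")
  expect_error(inhibition_timecourse(res, "S1S2", "SGLT1"), "not modeled")
})

test_that("a zero dose gives a flat zero inhibition profile", {
  res <- test_sim("inh_zero", "sotagliflozin", 0,
                  grid = seq(0, 24, by = 0.5))
  for (site in c("duodenum", "jejunum1", "S1S2", "S3")) {
    tr <- if (site == "S1S2") "SGLT2" else "SGLT1"
    p <- inhibition_timecourse(res, site, tr)
    expect_equal(max(abs(p$ratio)), 0, info = site)
  }
})

test_that("the reported maximum is the grid maximum and gut inhibition
           peaks during absorption", {
  res <- test_sim("inh_sota400", "sotagliflozin", 400,
                  params = test_calibration("sotagliflozin"))
  pk <- nca_sim(res)
  for (site in c("duodenum", "jejunum1")) {
    p <- inhibition_timecourse(res, site, "SGLT1")
    expect_equal(p$max_ratio, max(p$ratio))
    expect_equal(p$time_of_max, p$time[which.max(p$ratio)])
    expect_lte(p$time_of_max, pk$tmax)
    expect_true(all(p$ratio >= 0 & p$ratio <= 100))
  }
})

test_that("the inhibition summary covers all four sites", {
  res <- test_sim("inh_ertu5", "ertugliflozin", 5)
  s <- inhibition_summary(res)
  expect_setequal(s$site, c("duodenum", "jejunum1", "S1S2", "S3"))
  expect_equal(s$transporter[s$site == "S1S2"], "SGLT2")
  expect_true(all(s$max_ratio_pct >= 0 & s$max_ratio_pct <= 100))
})
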