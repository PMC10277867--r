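# independent transcription of the neutral-species partition equations,
# computed per tissue directly from the composition table; the oracle
# deliberately shares no code with compute_kp()
rodgers_oracle <- function(log_p, fup) {
  comp <- sgltsim:::.read_fixture("tissue_composition.csv")
  rownames(comp) <- comp$tissue
  P <- 10^log_p
  Pvo <- 10^(1.115 * log_p - 1.35)
  lipid <- function(P, f_nl, f_npl) P * f_nl + (0.3 * P + 0.7) * f_npl
  bracket <- 1 / fup - 1 - lipid(P, comp["plasma", "f_nl"],
                                 comp["plasma", "f_npl"])
  tissues <- setdiff(comp$tissue, "plasma")
  out <- numeric(length(tissues)); names(out) <- tissues
  for (t in tissues) {
    Pt <- if (t == "adipose") Pvo else P
    out[t] <- fup * (comp[t, "f_ew"] + comp[t, "f_iw"] +
                       lipid(Pt, comp[t, "f_nl"], comp[t, "f_npl"]) +
                       bracket * comp[t, "ra_alb"])
  }
  out
}

test_that("Kp matches an independent evaluation of the published equations", {
  sub <- reference_subject()
  for (nm in c("ertugliflozin", "sotagliflozin")) {
    cpd <- load_compound(nm)
    ps <- compute_kp(cpd, sub)
    oracle <- rodgers_oracle(cpd$log_p, cpd$fup)
    expect_equal(ps$kp[names(oracle)], oracle, tolerance = 1e-6,
                 info = nm)
  }
})

test_that("vanishing lipophilicity with no protein binding leaves the
           tissue-water partition", {
  sub <- reference_subject()
  cpd <- load_compound("ertugliflozin")
  cpd$log_p <- -12
  cpd$fup <- 1
  ps <- compute_kp(cpd, sub)
  comp <- sgltsim:::.read_fixture("tissue_composition.csv")
  rownames(comp) <- comp$tissue
  for (t in names(ps$kp)) {
    water <- comp[t, "f_ew"] + comp[t, "f_iw"]
    expect_lt(abs(ps$kp[[t]] - water) / water, 0.15)
  }
})

test_that("Vss is linear in tissue volumes and self-consistent", {
  sub <- reference_subject()
  cpd <- load_compound("empagliflozin")
  ps <- compute_kp(cpd, sub)
  expect_equal(vss_check(ps, sub), ps$vss, tolerance = 1e-12)

  sub2 <- sub
  tissues <- names(ps$kp)
  sub2$tissue_volumes[tissues] <- 2 * sub2$tissue_volumes[tissues]
  v_plasma <- sub$tissue_volumes["arterial"] + sub$tissue_volumes["venous"]
  plasma_term <- unname(v_plasma) / sub$body_weight
  expect_equal(vss_check(ps, sub2) - plasma_term,
               2 * (ps$vss - plasma_term), tolerance = 1e-12)
})

test_that("Kp grows monotonically with logP, tissue by tissue", {
  sub <- reference_subject()
  cpd <- load_compound("sotagliflozin")
  lp <- seq(1, 4.5, by = 0.5)
  kps <- sapply(lp, function(x) {
    cpd$log_p <- x
    compute_kp(cpd, sub)$kp
  })
  for (i in seq_len(nrow(kps))) {
    expect_true(all(diff(kps[i, ]) > 0),
                info = rownames(kps)[i])
  }
  # the source model's logP correction (3.6 -> 4.09) must raise Vss
  cpd$log_p <- 3.6; v1 <- compute_kp(cpd, sub)$vss
  cpd$log_p <- 4.09; v2 <- compute_kp(cpd, sub)$vss
  expect_gt(v2, v1)
})
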