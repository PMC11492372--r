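test_that("baseline EDL potential has the right polarity and trend", {
  # polarity opposite to the majority ion, for all four electrolytes
  for (build in list(naf, kcl, nacl, lif)) {
    sol <- build(1e-3)
    maj <- majority_ion(sol)
    expect_equal(sign(predict_Vbs(sol, pore23())), -sign(maj$valence))
  }

  # |V_bs| strictly decreasing over 1e-7..1e-1 M
  for (build in list(naf, kcl, nacl, lif)) {
    V <- vapply(conc_sweep, function(c) predict_Vbs(build(c), pore23()),
                numeric(1))
    expect_true(all(diff(abs(V)) < 0))
  }

  # changing the electrolyte rescales the curve without crossings:
  # the NaF/KCl ratio is the same at every concentration
  rat <- vapply(conc_sweep, function(c) {
    predict_Vbs(naf(c), pore23()) / predict_Vbs(kcl(c), pore23())
  }, numeric(1))
  expect_true(all(abs(rat / rat[1] - 1) < 0.05))

  # dual route at three concentrations
  for (c in c(1e-5, 1e-3, 1e-1)) {
    expect_equal(predict_Vbs(naf(c), pore23()), o_baseline_naf(c)$V,
                 tolerance = 1e-12)
  }
  # frozen reference value, 1 mM NaF in a 2.3 nm pore
  expect_equal(predict_Vbs(naf(1e-3), pore23()), -0.063662755367,
               tolerance = 1e-9)
})

test_that("baseline current is affine in the potential and sign-matched", {
  # affinity
  a <- 0.3; V1 <- -0.1; V2 <- -0.02
  expect_equal(baseline_current(a * V1 + (1 - a) * V2),
               a * baseline_current(V1) + (1 - a) * baseline_current(V2))

  # sign(I_bs) == sign(V_bs) across electrolytes, pores and concentrations
  for (build in list(naf, kcl, nacl, lif)) {
    for (r in c(1.7, 2.3, 4)) {
      for (c in conc_sweep) {
        V <- predict_Vbs(build(c), nanopore(r))
        expect_equal(sign(baseline_current(V)), sign(V))
      }
    }
  }

  # |I_bs| monotone decreasing with concentration
  I <- vapply(conc_sweep, function(c) baseline_current(predict_Vbs(naf(c), pore23())),
              numeric(1))
  expect_true(all(diff(abs(I)) < 0))

  # dual route
  for (V in c(-0.2, -0.05, -0.01)) {
    expect_equal(baseline_current(V), o_Ibs(V), tolerance = 1e-12)
  }
})

test_that("(V_bs, I_bs) pairs from all pores lie on one line", {
  pts <- do.call(rbind, lapply(c(1.7, 2.3, 4), function(r) {
    V <- vapply(conc_sweep, function(c) predict_Vbs(naf(c), nanopore(r)),
                numeric(1))
    cbind(V, baseline_current(V))
  }))
  fitl <- stats::lm(pts[, 2] ~ pts[, 1])
  expect_gt(suppressWarnings(summary(fitl)$r.squared), 1 - 1e-12)
})

test_that("drift velocity scales as mu V / L_Au", {
  maj <- majority_ion(naf(1e-3))
  expect_equal(drift_velocity(0, pore23(), maj), 0)
  v1 <- drift_velocity(-0.05, pore23(), maj)
  v2 <- drift_velocity(-0.05, nanopore(2.3, metal_length_nm = 10), maj)
  expect_equal(v2, v1 / 2)
  # hand computation: mu * V / L_Au, cation
  expect_equal(drift_velocity(-0.05, pore23(), maj),
               5.19e-8 * -0.05 / 5e-9)
  # missing mobility is a configuration error
  bad <- ion_species("X", 10, 0.1, 1)
  expect_error(drift_velocity(-0.05, pore23(), bad), "mobility")
})

test_that("charge density inverts the continuity relation exactly", {
  po <- pore23()
  I <- -1.04e-9; v <- -0.66
  n <- baseline_charge_density(I, v, po)
  expect_equal(n * po$A * v, I, tolerance = 1e-12)
  expect_equal(baseline_charge_density(0, v, po), 0)
  expect_error(baseline_charge_density(I, 0, po), "degenerate")

  # chained dual route at 1 mM NaF
  ob <- o_baseline_naf(1e-3)
  bs <- baseline_state(naf(1e-3), pore23())
  expect_equal(bs$n_bs, ob$n, tolerance = 1e-12)
  expect_true(bs$n_bs > 0)  # majority cations dominate the in-pore charge
})

test_that("EDL capacitance is the sweep slope and constant over the range", {
  po <- pore23()
  C <- edl_capacitance(naf(1e-3), po)
  # secant-slope oracle over the standard 20-point sweep
  expect_equal(C, o_CEDL_naf(2.3e-9), tolerance = 1e-9)
  # one constant per composition family: the operating concentration is
  # irrelevant
  expect_equal(edl_capacitance(naf(1e-5), po), C, tolerance = 1e-9)
  expect_equal(edl_capacitance(naf(1e-1), po), C, tolerance = 1e-9)
  expect_gt(C, 0)
  # local central-difference variant is step-size robust
  C1 <- edl_capacitance(naf(1e-3), po, method = "local", rel_step = 1e-6)
  C2 <- edl_capacitance(naf(1e-3), po, method = "local", rel_step = 5e-7)
  expect_equal(C1, C2, tolerance = 1e-5)
})

test_that("baseline sweep table carries instrument units and the full state", {
  sw <- baseline_sweep(naf(1), pore23(), conc_M = conc_sweep)
  expect_s3_class(sw, "tbl_df")
  expect_equal(nrow(sw), length(conc_sweep))
  expect_equal(sw$V_bs_mV[5] * 1e-3, predict_Vbs(naf(1e-3), pore23()))
  expect_true(all(diff(abs(sw$V_bs_mV)) < 0))
  expect_true(all(diff(abs(sw$I_bs_nA)) < 0))
})
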