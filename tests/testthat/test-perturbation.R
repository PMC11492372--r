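bs23 <- baseline_state(naf(1e-3), pore23())
setup_bs <- function() bs23

test_that("volumetric charge displacement is proportional to analyte volume", {
  bs <- setup_bs(); po <- pore23()
  expect_equal(delta_n_volume(analyte("null", 0, 0), bs, po), 0)
  a1 <- analyte("a", 0.5, 0, use_stokes = FALSE)
  a2 <- analyte("b", 0.5 * 2^(1 / 3), 0, use_stokes = FALSE)  # double volume
  expect_equal(delta_n_volume(a2, bs, po), 2 * delta_n_volume(a1, bs, po),
               tolerance = 1e-12)
  # opposite sign to the baseline charge density
  expect_lt(delta_n_volume(a1, bs, po) * bs$n_bs, 0)
  # an analyte bigger than the pore volume is rejected
  expect_error(delta_n_volume(analyte("big", 2.2, 0, use_stokes = FALSE),
                              bs, nanopore(2.3, length_nm = 2,
                                           metal_length_nm = 1)),
               "exceeds")
  # dual route, ceria-scale Stokes radius
  aS <- analyte("c", 1.27, 0, use_stokes = FALSE)
  expect_equal(delta_n_volume(aS, bs, po),
               o_dnV(bs$n_bs, 4 / 3 * pi * 1.27e-9^3, po$V_total),
               tolerance = 1e-12)
})

test_that("electrostatic compensation scales with analyte charge", {
  bs <- setup_bs(); po <- pore23()
  expect_equal(delta_n_electric(analyte("n", 1, 0), bs, po), 0)
  z <- c(1, 5, 28, 60, 112, 120)
  d <- vapply(z, function(zz) delta_n_electric(analyte("x", 1, zz), bs, po),
              numeric(1))
  expect_true(all(diff(abs(d)) > 0))  # monotone in |z|
  # sign flips with z, attract and repel both covered
  expect_equal(delta_n_electric(analyte("m", 1, -28), bs, po),
               -delta_n_electric(analyte("p", 1, 28), bs, po))
  expect_equal(delta_n_electric(analyte("p", 1, 28), bs, po),
               o_dnE(28, po$V_total), tolerance = 1e-12)
})

test_that("perturbation additivity and velocity/current closures hold", {
  bs <- setup_bs(); po <- pore23()
  an <- analyte("ceria", 1.27, 112, use_stokes = FALSE)
  dnV <- delta_n_volume(an, bs, po)
  dnE <- delta_n_electric(an, bs, po)
  ps <- predict_signals(naf(1e-3), po, an, baseline = bs)
  expect_identical(ps$dn, dnV + dnE)               # exact additivity
  expect_identical(ps$I_ps_A, ps$dI_A + ps$I_analyte_A)  # exact composition

  # unperturbed state: no velocity change
  expect_equal(delta_velocity(0, bs), 0)
  # linear in the baseline velocity
  bs2 <- bs; bs2$v_bs <- 2 * bs$v_bs
  expect_equal(delta_velocity(ps$dn, bs2), 2 * delta_velocity(ps$dn, bs))
  expect_error(delta_velocity(-bs$n_bs, bs), "degenerate")

  # zero perturbation gives zero current change
  expect_equal(delta_current(0, 0, bs, po), 0)
  # dual route for the chained perturbation
  expect_equal(ps$dv, o_dv(bs$v_bs, bs$n_bs, ps$dn), tolerance = 1e-12)
  expect_equal(ps$dI_A, o_dI(po$A, bs$n_bs, bs$v_bs, ps$dn), tolerance = 1e-12)
  # and the collapsed closed form
  expect_equal(ps$dI_A,
               -po$A * bs$v_bs * (bs$n_bs / (bs$n_bs + ps$dn)) * ps$dn,
               tolerance = 1e-12)
})

test_that("analyte charge density, velocity and current follow continuity", {
  po <- pore23()
  expect_equal(analyte_charge_density(analyte("n", 1, 0), po), 0)
  z <- c(-10, -1, 1, 28, 112)
  nn <- vapply(z, function(zz) analyte_charge_density(analyte("x", 1, zz), po),
               numeric(1))
  expect_equal(nn, z * nn[z == 1])   # linear in z

  expect_equal(analyte_velocity(1e-3, nanopore(2.3)), 5.5e-5)
  expect_equal(analyte_velocity(0.5e-3, po), 2 * analyte_velocity(1e-3, po))
  expect_error(analyte_velocity(0, po), "positive")

  an <- analyte("c", 1.27, 112, use_stokes = FALSE)
  expect_equal(analyte_current(an, 1e-3, po),
               o_Ian(112, 1e-3, po$A, po$V_total), tolerance = 1e-12)
  expect_equal(analyte_current(analyte("n", 1, 0), 1e-3, po), 0)
})

test_that("direct analyte current is negligible at millisecond times", {
  bs <- setup_bs(); po <- pore23()
  for (an in std_analytes()) {
    ps <- predict_signals(naf(1e-3), po, an, t_ic = 1e-3, baseline = bs)
    expect_lt(abs(ps$I_analyte_A) / abs(ps$I_ps_A), 1e-2)
  }
  ps <- predict_signals(naf(1e-3), po,
                        analyte("ceria", 1.27, 112, use_stokes = FALSE),
                        t_ic = 1e-3, baseline = bs)
  expect_lt(abs(ps$I_analyte_A) / abs(ps$I_ps_A), 1e-2)
})

test_that("EDL potential signal reflects total in-pore charge change", {
  bs <- setup_bs(); po <- pore23()
  expect_equal(potential_signal(0, 0, bs$C_EDL, po), 0)
  expect_error(potential_signal(1, 1, 0, po), "degenerate")
  an <- analyte("ceria", 1.27, 112, use_stokes = FALSE)
  ps <- predict_signals(naf(1e-3), po, an, baseline = bs)
  expect_equal(ps$V_ps_V,
               o_Vps(ps$dn, o_nan(112, po$V_total), po$V_total, bs$C_EDL),
               tolerance = 1e-12)

  # validation analytes stay in the +-1 mV band
  for (an in std_analytes()) {
    p <- predict_signals(naf(1e-3), po, an, baseline = bs)
    expect_lt(abs(p$V_ps_mV), 1)
  }
})

test_that("signal ordering and monotonicity match the model's phenomenology", {
  bs <- setup_bs(); po <- pore23()
  sig <- vapply(std_analytes(), function(an) {
    predict_signals(naf(1e-3), po, an, baseline = bs)$V_ps_mV
  }, numeric(1))
  names(sig) <- c("OA", "HQ", "AA", "CA")
  # hydroquinone most positive, citric acid most negative
  expect_equal(names(which.max(sig)), "HQ")
  expect_equal(names(which.min(sig)), "CA")

  # null analyte: both signals vanish
  null <- predict_signals(naf(1e-3), po, analyte("null", 0, 0), baseline = bs)
  expect_equal(null$I_ps_A, 0)
  expect_equal(null$V_ps_V, 0)

  # V_ps monotone increasing in z at fixed radius; I_ps moves the other way
  z <- seq(0, 120, by = 10)
  out <- t(vapply(z, function(zz) {
    p <- predict_signals(naf(1e-3), po, analyte("x", 1, zz, use_stokes = FALSE),
                         baseline = bs)
    c(p$V_ps_V, p$I_ps_A)
  }, numeric(2)))
  expect_true(all(diff(out[, 1]) > 0))
  expect_true(all(diff(out[, 2]) < 0))

  # baseline modulation: scaling the baseline state changes the signal
  bs_hi <- baseline_state(naf(1e-5), po)
  an <- analyte("ceria", 1.27, 112, use_stokes = FALSE)
  p1 <- predict_signals(naf(1e-3), po, an, baseline = bs)
  p2 <- predict_signals(naf(1e-5), po, an, baseline = bs_hi)
  expect_gt(abs(p2$I_ps_A - p1$I_ps_A) / abs(p1$I_ps_A), 1e-3)
})

test_that("forward model is continuous over the fitting domain", {
  bs <- setup_bs(); po <- pore23()
  r <- seq(0.1e-9, 2.0e-9, length.out = 400)
  f <- poresignal:::forward_signals(r, 28, bs, po)
  expect_true(all(is.finite(f$I_ps)) && all(is.finite(f$V_ps)))
  # no jumps: successive differences shrink with the grid
  expect_lt(max(abs(diff(f$V_ps))), 0.05 * diff(range(f$V_ps)))
  z <- seq(-200, 200, by = 1)
  g <- poresignal:::forward_signals(1e-9, z, bs, po)
  expect_lt(max(abs(diff(g$I_ps))), 0.05 * diff(range(g$I_ps)))
})
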