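sol <- naf(1e-3)
po <- pore23()
bs <- baseline_state(sol, po)

test_that("residual is zero at truth, reorder-invariant, and hand-checkable", {
  obs <- tibble::tibble(I_ps_nA = c(-0.3, -0.32, -0.28),
                        V_ps_mV = c(30, 33, 27))
  pred <- list(I_ps = -0.30e-9, V_ps = 30e-3)
  # observed == predicted gives zero
  expect_equal(residual_error(obs[1, ], list(I_ps = -0.3e-9, V_ps = 30e-3)), 0)
  # reorder invariance
  expect_equal(residual_error(obs, pred), residual_error(obs[c(3, 1, 2), ], pred))
  # spreadsheet oracle on the 3-event toy table
  by_hand <- mean(((c(-0.3, -0.32, -0.28) + 0.3) / abs(c(-0.3, -0.32, -0.28)))^2) +
    mean(((c(30, 33, 27) - 30) / c(30, 33, 27))^2)
  expect_equal(residual_error(obs, pred), by_hand)
  # zero observation switches to absolute error with a warning
  obs0 <- tibble::tibble(I_ps_nA = 0, V_ps_mV = 1)
  expect_warning(residual_error(obs0, pred), "absolute")
})

test_that("noise-free signals are recovered exactly to grid resolution", {
  spec <- fit_spec()
  for (truth in list(c(0.92, 28), c(1.27, 112), c(0.5, -20))) {
    ev <- simulate_events(sol, po, analyte("t", truth[1], truth[2]),
                          n_events = 3, noise_rel = 0, seed = 7, baseline = bs)
    f <- fit_analyte(ev, sol, po, spec, baseline = bs)
    step_nm <- diff(seq(spec$r_range_nm[1], min(spec$r_range_nm[2], 2.3 * 0.999),
                        length.out = spec$r_steps))[1]
    expect_lt(abs(f$r_hat * 1e9 - truth[1]), step_nm)
    expect_equal(f$z_hat, as.integer(truth[2]))
    # brute-force check: the surface's global minimum sits at the truth
    surf_min <- f$residual_surface[which.min(f$residual_surface$residual), ]
    expect_equal(surf_min$z, truth[2])
    expect_lt(abs(surf_min$r_nm - truth[1]), step_nm)
  }
})

test_that("noisy recovery stays within stated tolerances", {
  ev <- simulate_events(sol, po, analyte("c", 1.27, 112, use_stokes = FALSE),
                        n_events = 50, noise_rel = 0.05, seed = 11,
                        baseline = bs)
  f <- fit_analyte(ev, sol, po, fit_spec(use_stokes = FALSE), baseline = bs)
  expect_lt(abs(f$r_hat * 1e9 - 1.27) / 1.27, 0.10)
  expect_lt(abs(f$z_hat - 112) / 112, 0.15)
})

test_that("all-zero signals fall back to the degenerate corner", {
  obs <- tibble::tibble(I_ps_nA = c(0, 0), V_ps_mV = c(0, 0))
  f <- suppressWarnings(fit_analyte(obs, sol, po, fit_spec(), baseline = bs))
  expect_true(f$degenerate)
  expect_equal(f$r_hat * 1e9, 0.1, tolerance = 1e-9)
  expect_equal(f$z_hat, 0L)
})

test_that("series fits recover distinct, identical and monotone groups", {
  evs <- simulate_series(sol, po, true_r_nm = c(0.92, 1.27),
                         true_z = c(28, 112), n_events = 3, noise_rel = 0,
                         seed = 5)
  res <- fit_series(evs, sol, po, fit_spec())
  expect_equal(res$z_hat, c(28L, 112L))
  expect_true(res$r_hat_nm[1] < res$r_hat_nm[2])

  # identical groups give identical fits
  ev1 <- simulate_events(sol, po, analyte("a", 0.92, 28), n_events = 3,
                         noise_rel = 0, seed = 5, baseline = bs)
  two <- dplyr::bind_rows(
    dplyr::mutate(ev1, condition = "g1"),
    dplyr::mutate(ev1, condition = "g2")
  )
  res2 <- fit_series(two, sol, po, fit_spec())
  expect_equal(res2$r_hat_nm[1], res2$r_hat_nm[2])
  expect_equal(res2$z_hat[1], res2$z_hat[2])

  # monotone oxidation series in true charge is recovered monotone
  evm <- simulate_series(sol, po, true_r_nm = rep(1.0, 4),
                         true_z = c(10, 28, 60, 112), n_events = 20,
                         noise_rel = 0.05, seed = 9)
  resm <- fit_series(evm, sol, po, fit_spec())
  expect_true(all(diff(resm$z_hat) > 0))
})

test_that("Stokes-mode fits give smaller bare radii than bare-mode fits", {
  # data from a bare-radius particle; fitting with a water layer must
  # attribute part of the size to the shell
  ev <- simulate_events(sol, po, analyte("c", 1.0, 40, use_stokes = FALSE),
                        n_events = 5, noise_rel = 0, seed = 13, baseline = bs)
  f_bare <- fit_analyte(ev, sol, po, fit_spec(use_stokes = FALSE), baseline = bs)
  f_stokes <- fit_analyte(ev, sol, po, fit_spec(use_stokes = TRUE), baseline = bs)
  expect_lt(f_stokes$r_hat, f_bare$r_hat)
})

test_that("fit accessors are tidy", {
  ev <- simulate_events(sol, po, analyte("a", 0.92, 28), n_events = 3,
                        noise_rel = 0, seed = 5, baseline = bs)
  f <- fit_analyte(ev, sol, po, fit_spec(), baseline = bs)
  td <- tidy(f)
  expect_equal(td$term, c("radius_nm", "valence"))
  expect_true(all(td$low <= td$estimate & td$estimate <= td$high))
  gl <- glance(f)
  expect_equal(gl$n_events, 3L)
  expect_s3_class(autoplot(f), "ggplot")
})
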