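# Inverse fitting: recover analyte radius and valence charge from measured
# (I_ps, V_ps) signal sets by exhaustive grid search plus local refinement.

#' Fit specification
#'
#' Grids, mode flags and residual weights for [fit_analyte()].
#'
#' @param r_range_nm Radius grid range, nm.
#' @param r_steps Number of radius grid points.
#' @param z_range Integer valence grid range.
#' @param z_step Valence grid step (integer).
#' @param use_stokes Fit with the Stokes radius (bare radius otherwise).
#' @param water_layer_nm Water-layer thickness for the Stokes radius, nm.
#' @param w_I,w_V Residual weights of the current and potential channels.
#'   Set one of them to 0 to fit a single channel alone.
#' @param refine Locally refine the radius (continuous) around the grid
#'   minimum?
#' @return A list of class `"fit_spec"`.
#' @export
fit_spec <- function(r_range_nm = c(0.1, 4.0), r_steps = 79,
                     z_range = c(-200L, 200L), z_step = 1L,
                     use_stokes = TRUE, water_layer_nm = 0.14,
                     w_I = 1, w_V = 1, refine = TRUE) {
  stopifnot(r_steps >= 2, r_range_nm[1] > 0, r_range_nm[2] > r_range_nm[1],
            z_step >= 1, w_I >= 0, w_V >= 0, w_I + w_V > 0)
  structure(list(r_range_nm = r_range_nm, r_steps = r_steps,
                 z_range = as.integer(z_range), z_step = as.integer(z_step),
                 use_stokes = isTRUE(use_stokes),
                 water_layer_nm = water_layer_nm,
                 w_I = w_I, w_V = w_V, refine = isTRUE(refine)),
            class = "fit_spec")
}

# Closed-form forward model on vectors of (r, z), given one baseline state.
# r in metres (bare radius); returns list(I_ps, V_ps) in SI.
forward_signals <- function(r, z, baseline, pore, use_stokes = TRUE,
                            water_layer = 0.14e-9, t_ic = 1e-3,
                            screening = model_constants()$screening) {
  r_eff <- ifelse(use_stokes & r > 0, r + water_layer, r)
  V_an <- 4 / 3 * pi * r_eff^3
  dn <- -(baseline$n_bs * V_an + screening * z * .e_charge) / pore$V_total
  n_ps <- baseline$n_bs + dn
  dI <- -pore$A * baseline$v_bs * (baseline$n_bs / n_ps) * dn
  I_an <- (z * .e_charge / pore$V_total) * pore$A * (pore$L / t_ic)
  V_ps <- -(pore$V_total * dn + z * .e_charge) / baseline$C_EDL
  list(I_ps = dI + I_an, V_ps = V_ps)
}

#' Weighted residual between observed and predicted signals
#'
#' Mean over observations of the weighted squared relative errors in the
#' current and potential channels:
#' `mean( w_I ((I_i - I_pred)/|I_i|)^2 + w_V ((V_i - V_pred)/|V_i|)^2 )`.
#' Scale-free, so nA-scale currents and mV-scale potentials contribute
#' comparably. An observation of exactly zero in a channel switches that
#' term to an absolute error (with a warning), since a relative error is
#' undefined there.
#'
#' @param observed Data frame with `I_ps_nA` and `V_ps_mV` columns.
#' @param predicted List or one-row data frame with `I_ps` and `V_ps` in SI
#'   units (A, V); vectors are allowed and give a residual per prediction.
#' @param w_I,w_V Channel weights.
#' @return Dimensionless residual(s), >= 0; invariant under reordering the
#'   observations.
#' @export
residual_error <- function(observed, predicted, w_I = 1, w_V = 1) {
  stopifnot(is.data.frame(observed), nrow(observed) >= 1)
  I_obs <- observed$I_ps_nA * 1e-9
  V_obs <- observed$V_ps_mV * 1e-3
  s_I <- abs(I_obs)
  s_V <- abs(V_obs)
  if (any(s_I == 0) && w_I > 0) {
    warning("zero observed current signal: using absolute error for that event")
    s_I[s_I == 0] <- 1
  }
  if (any(s_V == 0) && w_V > 0) {
    warning("zero observed potential signal: using absolute error for that event")
    s_V[s_V == 0] <- 1
  }
  # residual(pred) = mean_i wI((Ii - Ip)/sIi)^2 + wV((Vi - Vp)/sVi)^2,
  # expanded into moments so a whole grid of predictions is vectorised
  m0_I <- mean(1 / s_I^2); m1_I <- mean(I_obs / s_I^2); m2_I <- mean(I_obs^2 / s_I^2)
  m0_V <- mean(1 / s_V^2); m1_V <- mean(V_obs / s_V^2); m2_V <- mean(V_obs^2 / s_V^2)
  Ip <- predicted$I_ps
  Vp <- predicted$V_ps
  w_I * (Ip^2 * m0_I - 2 * Ip * m1_I + m2_I) +
    w_V * (Vp^2 * m0_V - 2 * Vp * m1_V + m2_V)
}

#' Fit analyte radius and charge to measured signals
#'
#' Exhaustive grid search over (radius, valence) followed by a local
#' continuous refinement of the radius at the best valence. Deterministic for
#' a fixed specification; ties are broken toward the smaller radius, then the
#' smaller |valence|.
#'
#' @param observed Data frame of events with columns `I_ps_nA`, `V_ps_mV`
#'   and optionally `t_ic_ms` (its mean feeds the negligible direct analyte
#'   current; 1 ms is assumed when absent).
#' @param solution An [electrolyte()] describing the measurement condition.
#' @param pore A [nanopore()].
#' @param spec A [fit_spec()].
#' @param baseline Optional precomputed [baseline_state()].
#' @return An object of class `"analyte_fit"`: list with `r_hat` (m),
#'   `z_hat`, `residual`, `residual_surface` (tibble `r_nm`, `z`,
#'   `residual`), `degenerate` flag, `spec`, `n_events`.
#' @export
#' @examples
#' sol <- electrolyte(Na = 1e-3, F = 1e-3)
#' po <- nanopore(2.3)
#' ev <- simulate_events(sol, po, analyte("x", 0.9, 28), n_events = 5,
#'                       noise_rel = 0, seed = 1)
#' fit <- fit_analyte(ev, sol, po, fit_spec(r_steps = 20))
#' glance(fit)
fit_analyte <- function(observed, solution, pore, spec = fit_spec(),
                        baseline = NULL) {
  stopifnot(is.data.frame(observed), inherits(spec, "fit_spec"))
  if (nrow(observed) < 1) stop("need at least one observation", call. = FALSE)
  if (is.null(baseline)) baseline <- baseline_state(solution, pore)

  degenerate <- all(observed$I_ps_nA == 0) && all(observed$V_ps_mV == 0)
  if (degenerate)
    warning("all observed signals are zero: the fit is degenerate and ",
            "returns the minimal-radius, zero-charge corner")

  t_ic <- if ("t_ic_ms" %in% names(observed)) mean(observed$t_ic_ms) * 1e-3
          else 1e-3
  r_max <- min(spec$r_range_nm[2], pore$r_np * 1e9 * 0.999)
  r_grid <- seq(spec$r_range_nm[1], r_max, length.out = spec$r_steps) * 1e-9
  z_grid <- seq(spec$z_range[1], spec$z_range[2], by = spec$z_step)

  grid <- expand.grid(r = r_grid, z = z_grid)
  pred <- forward_signals(grid$r, grid$z, baseline, pore,
                          use_stokes = spec$use_stokes,
                          water_layer = spec$water_layer_nm * 1e-9,
                          t_ic = t_ic)
  res <- residual_error(observed, pred, w_I = spec$w_I, w_V = spec$w_V)
  if (all(!is.finite(res)))
    stop("forward model failed over the whole grid", call. = FALSE)

  if (degenerate) {
    # a null signal carries no information: report the zero-charge,
    # minimal-radius corner
    corner <- which(grid$r == r_grid[1] & grid$z == 0)
    r_hat <- r_grid[1]; z_hat <- 0L; res_hat <- res[corner]
  } else {
    best <- which(res == min(res, na.rm = TRUE))
    if (length(best) > 1) {
      ord <- order(grid$r[best], abs(grid$z[best]))
      best <- best[ord[1]]
    }
    r_hat <- grid$r[best]
    z_hat <- grid$z[best]
    res_hat <- res[best]
  }

  if (spec$refine && !degenerate) {
    # the relative residual is steep near signal zero-crossings, so the
    # radius is refined continuously for every competitive valence, not just
    # the best grid cell
    step <- diff(r_grid[1:2])
    res_mat <- matrix(res, nrow = length(r_grid))
    z_min <- apply(res_mat, 2, min, na.rm = TRUE)
    cand <- z_grid[z_min <= stats::quantile(z_min, 0.1, na.rm = TRUE) |
                     abs(z_grid - z_hat) <= 2 * spec$z_step]
    for (zz in cand) {
      r0 <- r_grid[which.min(res_mat[, match(zz, z_grid)])]
      f <- function(rr) {
        p <- forward_signals(rr, zz, baseline, pore,
                             use_stokes = spec$use_stokes,
                             water_layer = spec$water_layer_nm * 1e-9,
                             t_ic = t_ic)
        residual_error(observed, p, w_I = spec$w_I, w_V = spec$w_V)
      }
      opt <- stats::optimize(f, c(max(r_grid[1], r0 - step),
                                  min(max(r_grid), r0 + step)), tol = 1e-15)
      improve <- opt$objective < res_hat * (1 - 1e-12)
      tie <- abs(opt$objective - res_hat) <= res_hat * 1e-12 &&
        (abs(zz) < abs(z_hat) || (abs(zz) == abs(z_hat) && opt$minimum < r_hat))
      if (improve || tie) {
        r_hat <- opt$minimum
        z_hat <- zz
        res_hat <- opt$objective
      }
    }
  }

  surface <- tibble::tibble(r_nm = grid$r * 1e9, z = grid$z, residual = res)
  structure(list(r_hat = r_hat, z_hat = as.integer(z_hat),
                 residual = res_hat, residual_surface = surface,
                 degenerate = degenerate, spec = spec,
                 n_events = nrow(observed), baseline = baseline, pore = pore),
            class = "analyte_fit")
}

#' @export
print.analyte_fit <- function(x, ...) {
  cat(sprintf("<analyte_fit> r = %.3g nm, z = %+d, residual = %.3g (n = %d)%s\n",
              x$r_hat * 1e9, x$z_hat, x$residual, x$n_events,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an analyte fit
#'
#' @param x An `analyte_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter (`radius_nm`,
#'   `valence`) and a crude grid interval (cells whose residual lies within
#'   5% of the surface range above the minimum).
#' @method tidy analyte_fit
#' @export
tidy.analyte_fit <- function(x, ...) {
  s <- x$residual_surface
  thr <- min(s$residual) + 0.05 * diff(range(s$residual))
  near <- s[s$residual <= thr, ]
  tibble::tibble(
    term = c("radius_nm", "valence"),
    estimate = c(x$r_hat * 1e9, x$z_hat),
    low = c(min(near$r_nm), min(near$z)),
    high = c(max(near$r_nm), max(near$z))
  )
}

#' One-row summary of an analyte fit
#'
#' @param x An `analyte_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `r_hat_nm`, `z_hat`, `residual`, `n_events`,
#'   `degenerate`.
#' @method glance analyte_fit
#' @export
glance.analyte_fit <- function(x, ...) {
  tibble::tibble(r_hat_nm = x$r_hat * 1e9, z_hat = x$z_hat,
                 residual = x$residual, n_events = x$n_events,
                 degenerate = x$degenerate)
}

#' Fit each condition of a grouped event table
#'
#' Events are grouped by the `condition` column (a titration step, for
#' instance) and fitted independently; failures in one group are reported
#' without stopping the others.
#'
#' @param observed Data frame with a `condition` column plus the event
#'   columns of [fit_analyte()].
#' @param solution An [electrolyte()].
#' @param pore A [nanopore()].
#' @param spec A [fit_spec()].
#' @return A tibble with one row per condition: `condition`, `r_hat_nm`,
#'   `z_hat`, `residual`, `n_events`, `error` (NA when the fit succeeded).
#' @export
fit_series <- function(observed, solution, pore, spec = fit_spec()) {
  stopifnot("condition" %in% names(observed))
  baseline <- baseline_state(solution, pore)
  groups <- split(tibble::as_tibble(observed), observed$condition)
  purrr::map_dfr(names(groups), function(g) {
    out <- tryCatch({
      f <- fit_analyte(groups[[g]], solution, pore, spec, baseline = baseline)
      tibble::tibble(condition = g, r_hat_nm = f$r_hat * 1e9,
                     z_hat = f$z_hat, residual = f$residual,
                     n_events = f$n_events, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(condition = g, r_hat_nm = NA_real_, z_hat = NA_integer_,
                     residual = NA_real_, n_events = nrow(groups[[g]]),
                     error = conditionMessage(e))
    })
    out
  })
}
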