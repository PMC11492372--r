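#' Charge-density change from volumetric occlusion
#'
#' The analyte excludes its own volume from the pore, displacing the
#' baseline-state charge it would have contained (the classical blockade
#' effect): `dn_V = -n_bs * V_analyte / V_total`. Proportional to the
#' occluded volume and opposite in sign to the baseline charge density.
#'
#' @param analyte An [analyte()].
#' @param baseline A [baseline_state()].
#' @param pore A [nanopore()].
#' @return Charge-density change, C/m^3.
#' @export
delta_n_volume <- function(analyte, baseline, pore) {
  stopifnot(inherits(analyte, "pore_analyte"), inherits(pore, "nanopore"))
  if (analyte$V_analyte >= pore$V_total)
    stop("analyte volume exceeds the pore volume", call. = FALSE)
  -baseline$n_bs * analyte$V_analyte / pore$V_total
}

#' Charge-density change from electrostatic compensation
#'
#' Ions are attracted to (or repelled from) the charged analyte, accumulating
#' a compensatory charge of opposite sign in the pore:
#' `dn_E = -kappa * z_analyte * e / V_total`. The screening factor `kappa`
#' (default 1.15, see [model_constants()]) exceeds 1: in strong confinement
#' the compensation overshoots the analyte's own charge (EDL overscreening).
#' The expression holds whether ions are attracted or repelled, and vanishes
#' for a neutral analyte.
#'
#' @inheritParams delta_n_volume
#' @param screening Compensation factor `kappa`.
#' @return Charge-density change, C/m^3.
#' @export
delta_n_electric <- function(analyte, baseline, pore,
                             screening = model_constants()$screening) {
  stopifnot(inherits(analyte, "pore_analyte"), inherits(pore, "nanopore"))
  -screening * analyte$z_analyte * .e_charge / pore$V_total
}

#' Drift-velocity change in the perturbed state
#'
#' Empirical velocity closure of the model: the carrier velocity responds
#' inverse-quadratically to the perturbed charge density,
#' `v_ps = v_bs (n_bs / n_ps)^2` with `n_ps = n_bs + dn_bs`, so
#' `dv_bs = v_bs [(n_bs / n_ps)^2 - 1]`. Zero when the charge density is
#' unperturbed, and linear in the baseline velocity.
#'
#' @param delta_n Total charge-density perturbation `dn_bs`, C/m^3.
#' @param baseline A [baseline_state()].
#' @return Velocity change, m/s.
#' @export
delta_velocity <- function(delta_n, baseline) {
  n_ps <- baseline$n_bs + delta_n
  if (any(n_ps == 0)) stop("degenerate state: n_ps = 0", call. = FALSE)
  baseline$v_bs * ((baseline$n_bs / n_ps)^2 - 1)
}

#' Electrolyte-current change in the perturbed state
#'
#' Same continuity form as the baseline current, applied to the perturbed
#' state: `dI_bs = A (n_ps v_ps - n_bs v_bs)`, with the cross term between
#' the density and velocity perturbations included. Under the model's
#' velocity closure this equals `-A v_bs (n_bs / n_ps) dn_bs`.
#'
#' @param delta_n Charge-density perturbation, C/m^3.
#' @param delta_v Velocity perturbation, m/s.
#' @param baseline A [baseline_state()].
#' @param pore A [nanopore()].
#' @return Current change, A.
#' @export
delta_current <- function(delta_n, delta_v, baseline, pore) {
  stopifnot(inherits(pore, "nanopore"))
  n_ps <- baseline$n_bs + delta_n
  v_ps <- baseline$v_bs + delta_v
  pore$A * (n_ps * v_ps - baseline$n_bs * baseline$v_bs)
}

#' Analyte charge density
#'
#' The analyte treated as a single charged particle spread over the pore
#' volume: `n_analyte = z_analyte * e / V_total`.
#'
#' @param analyte An [analyte()].
#' @param pore A [nanopore()].
#' @return Charge density, C/m^3 (signed); linear in the valence.
#' @export
analyte_charge_density <- function(analyte, pore) {
  stopifnot(inherits(analyte, "pore_analyte"), inherits(pore, "nanopore"))
  analyte$z_analyte * .e_charge / pore$V_total
}

#' Analyte drift velocity from the translocation time
#'
#' `v_analyte = L / t_ic`: total pore length over the event duration measured
#' as the FDHM of the current spike.
#'
#' @param t_ic Translocation time, s (> 0). Vectorised.
#' @param pore A [nanopore()].
#' @return Velocity magnitude, m/s.
#' @export
analyte_velocity <- function(t_ic, pore) {
  stopifnot(inherits(pore, "nanopore"))
  if (any(!is.finite(t_ic)) || any(t_ic <= 0))
    stop("t_ic must be positive", call. = FALSE)
  pore$L / t_ic
}

#' Direct current contribution of the analyte
#'
#' `I_analyte = n_analyte * A * v_analyte`, the continuity form applied to
#' the analyte itself. Because the analyte drifts orders of magnitude slower
#' than the electrolyte carriers, this term is negligible against the
#' electrolyte-current change at millisecond translocation times.
#'
#' @param analyte An [analyte()].
#' @param t_ic Translocation time, s.
#' @param pore A [nanopore()].
#' @return Current, A (signed).
#' @export
analyte_current <- function(analyte, t_ic, pore) {
  analyte_charge_density(analyte, pore) * pore$A * analyte_velocity(t_ic, pore)
}

#' EDL potential signal
#'
#' The EDL potential responds to the change in total in-pore charge through
#' the EDL capacitance, with the gating sign of the metal layer:
#' `V_ps = -V_total (dn_bs + n_analyte) / C_EDL` (`C_EDL` a positive
#' magnitude). Zero when there is neither a charge-density perturbation nor
#' an analyte charge.
#'
#' @param delta_n Charge-density perturbation `dn_bs`, C/m^3.
#' @param n_analyte Analyte charge density, C/m^3.
#' @param C_EDL EDL capacitance magnitude, F (non-zero).
#' @param pore A [nanopore()].
#' @return Potential signal, V.
#' @export
potential_signal <- function(delta_n, n_analyte, C_EDL, pore) {
  stopifnot(inherits(pore, "nanopore"))
  if (any(C_EDL == 0)) stop("degenerate capacitance: C_EDL = 0", call. = FALSE)
  -pore$V_total * (delta_n + n_analyte) / C_EDL
}

#' Forward prediction of the perturbed-state signals
#'
#' Composes the whole perturbation chain: baseline state, volumetric and
#' electrostatic charge-density changes, velocity change, electrolyte-current
#' change plus the analyte's direct current (`I_ps = dI_bs + I_analyte`), and
#' the EDL potential signal. Deterministic.
#'
#' @param solution An [electrolyte()].
#' @param pore A [nanopore()].
#' @param analyte An [analyte()].
#' @param t_ic Translocation time, s (default 1 ms; it only affects the
#'   negligible direct analyte current, and the default is flagged in the
#'   output).
#' @param screening Electrostatic compensation factor.
#' @param baseline Optional precomputed [baseline_state()] (saves the sweep
#'   capacitance fit when predicting many analytes for one condition).
#' @return A one-row tibble: `I_ps_A`, `V_ps_mV`, `I_ps_nA`, and the
#'   components `dn_V`, `dn_E`, `dn`, `dv`, `dI_A`, `I_analyte_A`, `V_ps_V`,
#'   plus `t_ic_s` and `t_ic_default`.
#' @export
#' @examples
#' sol <- electrolyte(Na = 1e-3, F = 1e-3)
#' predict_signals(sol, nanopore(2.3), analyte("CA", 0.37, -3))
predict_signals <- function(solution, pore, analyte, t_ic = NULL,
                            screening = model_constants()$screening,
                            baseline = NULL) {
  stopifnot(inherits(analyte, "pore_analyte"))
  if (is.null(baseline)) baseline <- baseline_state(solution, pore)
  t_default <- is.null(t_ic)
  if (t_default) t_ic <- 1e-3
  dn_V <- delta_n_volume(analyte, baseline, pore)
  dn_E <- delta_n_electric(analyte, baseline, pore, screening = screening)
  dn <- dn_V + dn_E
  dv <- delta_velocity(dn, baseline)
  dI <- delta_current(dn, dv, baseline, pore)
  n_an <- analyte_charge_density(analyte, pore)
  I_an <- analyte_current(analyte, t_ic, pore)
  I_ps <- dI + I_an
  V_ps <- potential_signal(dn, n_an, baseline$C_EDL, pore)
  tibble::tibble(
    I_ps_A = I_ps, V_ps_V = V_ps,
    I_ps_nA = I_ps * 1e9, V_ps_mV = V_ps * 1e3,
    dn_V = dn_V, dn_E = dn_E, dn = dn, dv = dv,
    dI_A = dI, I_analyte_A = I_an,
    t_ic_s = t_ic, t_ic_default = t_default
  )
}
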