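#' Baseline-state EDL potential
#'
#' Empirical baseline relationship of the model:
#' \deqn{V_{bs} = -\mathrm{sgn}(z_{maj}) \frac{RT}{F} P_{bs}
#'   \ln\!\left[\frac{a_{nanopore}}{a_{reservoir}}\cdot
#'              \frac{c^\circ}{a_{reservoir}}\right]}
#' with \eqn{c^\circ = 1} mol/L. The sign function and the leading negative
#' sign force a polarity opposite to the majority ion; the logarithmic
#' dependence on the reservoir activity makes the magnitude decrease
#' monotonically as the electrolyte concentration rises, and the partition
#' coefficient `P_bs` carries the electrolyte- and pore-size dependence.
#'
#' @param solution An [electrolyte()].
#' @param pore A [nanopore()].
#' @param L_C Characteristic length for the partition coefficient, m.
#' @param majority_override Optional majority-ion override name.
#' @return Baseline EDL potential, V (signed).
#' @export
#' @examples
#' predict_Vbs(electrolyte(Na = 1e-3, F = 1e-3), nanopore(2.3))
predict_Vbs <- function(solution, pore, L_C = model_constants()$L_C,
                        majority_override = NULL) {
  stopifnot(inherits(solution, "electrolyte"), inherits(pore, "nanopore"))
  maj <- majority_ion(solution, override = majority_override)
  act <- suppressMessages(
    ionic_activities(solution, majority_override = majority_override)
  )
  if (act$a_nanopore <= 0 || act$a_reservoir <= 0)
    stop("zero ionic activity", call. = FALSE)
  P <- suppressMessages(partition_coefficient(
    solution, pore, L_C = L_C, majority_override = majority_override
  ))
  kT_e <- .R_gas * solution$temperature / .Faraday
  -sign(maj$valence) * kT_e * P *
    log((act$a_nanopore / act$a_reservoir) * (1 / act$a_reservoir))
}

#' Baseline-state ionic current
#'
#' The device's linear baseline current-potential relationship,
#' `I_bs = G_pore * V_bs + I0_pore` (SI units: amperes and volts). The
#' coefficients are the model calibration constants in [model_constants()].
#'
#' @param V_bs Baseline EDL potential, V. Vectorised.
#' @param const Model constants, see [model_constants()].
#' @return Baseline ionic current, A.
#' @export
baseline_current <- function(V_bs, const = model_constants()) {
  stopifnot(all(is.finite(V_bs)))
  const$G_pore * V_bs + const$I0_pore
}

#' Baseline drift velocity of the majority ion
#'
#' `v_bs = sgn(z_maj) * mu_ion * E` with the driving field `E = V_bs / L_Au`
#' taken over the metal layer. Ions drift along the field scaled by the sign
#' of their charge, so the majority carrier velocity follows the polarity of
#' both the potential and the ion.
#'
#' @param V_bs Baseline EDL potential, V.
#' @param pore A [nanopore()].
#' @param majority One-row species tibble (see [majority_ion()]); must carry
#'   a mobility.
#' @return Drift velocity, m/s (signed).
#' @export
drift_velocity <- function(V_bs, pore, majority) {
  stopifnot(inherits(pore, "nanopore"))
  mu <- majority$mobility
  if (is.na(mu) || mu <= 0)
    stop("majority ion '", majority$name,
         "' has no mobility; set one in the ion table", call. = FALSE)
  E <- V_bs / pore$L_Au
  sign(majority$valence) * mu * E
}

#' Baseline charge density inside the pore
#'
#' Algebraic inverse of the current continuity relation `I = n A v`:
#' `n_bs = I_bs / (A v_bs)`. The round trip `n_bs * A * v_bs` returns `I_bs`
#' to machine precision.
#'
#' @param I_bs Baseline current, A.
#' @param v_bs Baseline drift velocity, m/s (non-zero).
#' @param pore A [nanopore()].
#' @return Charge density, C/m^3.
#' @export
baseline_charge_density <- function(I_bs, v_bs, pore) {
  stopifnot(inherits(pore, "nanopore"))
  if (any(v_bs == 0)) stop("degenerate state: v_bs = 0", call. = FALSE)
  I_bs / (pore$A * v_bs)
}

#' EDL capacitance
#'
#' Derivative of the baseline in-pore charge `Q = V_total * n_bs` with
#' respect to the EDL potential. The default (`method = "sweep"`) takes the
#' slope of an ordinary least-squares fit of `Q` against `V_bs` over the
#' composition's standard concentration sweep (1e-7 to 1e-1 M total, log
#' spaced), which yields one constant capacitance per electrolyte family and
#' pore — the charge-potential relation of the model is close to linear over
#' that operating range. `method = "local"` instead takes a central finite
#' difference of the chain at the supplied solution's own operating point
#' (relative step 1e-6 on `V_bs`). The returned value is a positive magnitude;
#' the signal model applies the EDL's gating sign explicitly (see
#' [potential_signal()]).
#'
#' @param solution An [electrolyte()].
#' @param pore A [nanopore()].
#' @param method `"sweep"` (default) or `"local"`.
#' @param conc_range Total-concentration range of the sweep, mol/L.
#' @param n_sweep Number of sweep points.
#' @param rel_step Relative step of the local central difference.
#' @param majority_override Optional majority-ion override name.
#' @return Capacitance magnitude, F.
#' @export
#' @examples
#' edl_capacitance(electrolyte(Na = 1e-3, F = 1e-3), nanopore(2.3))
edl_capacitance <- function(solution, pore, method = c("sweep", "local"),
                            conc_range = c(1e-7, 1e-1), n_sweep = 20,
                            rel_step = 1e-6, majority_override = NULL) {
  stopifnot(inherits(solution, "electrolyte"), inherits(pore, "nanopore"))
  method <- match.arg(method)
  maj <- suppressMessages(majority_ion(solution, override = majority_override))

  charge_at <- function(V) {
    I <- baseline_current(V)
    v <- drift_velocity(V, pore, maj)
    pore$V_total * baseline_charge_density(I, v, pore)
  }

  if (method == "local") {
    V0 <- predict_Vbs(solution, pore, majority_override = majority_override)
    h <- abs(V0) * rel_step
    C <- (charge_at(V0 + h) - charge_at(V0 - h)) / (2 * h)
  } else {
    # scale the composition across the operating range; ratios fixed
    totals <- 10^seq(log10(conc_range[1] * 2), log10(conc_range[2] * 2),
                     length.out = n_sweep)
    V <- vapply(totals, function(tt) {
      predict_Vbs(rescale_electrolyte(solution, tt), pore,
                  majority_override = majority_override)
    }, numeric(1))
    Q <- vapply(V, charge_at, numeric(1))
    C <- stats::cov(V, Q) / stats::var(V)
  }
  if (!is.finite(C)) stop("non-finite capacitance", call. = FALSE)
  abs(C)
}

#' Full baseline state
#'
#' Evaluates the whole baseline chain for one solution and pore: EDL
#' potential, ionic current, driving field, drift velocity, charge density
#' and EDL capacitance.
#'
#' @inheritParams predict_Vbs
#' @param cedl_method Capacitance method passed to [edl_capacitance()].
#' @return An object of class `"baseline_state"`: a list with `V_bs` (V),
#'   `I_bs` (A), `E` (V/m), `v_bs` (m/s), `n_bs` (C/m^3), `C_EDL` (F) and
#'   the `majority` species row.
#' @export
#' @examples
#' baseline_state(electrolyte(Na = 1e-3, F = 1e-3), nanopore(2.3))
baseline_state <- function(solution, pore, L_C = model_constants()$L_C,
                           majority_override = NULL, cedl_method = "sweep") {
  maj <- suppressMessages(majority_ion(solution, override = majority_override))
  V_bs <- predict_Vbs(solution, pore, L_C = L_C,
                      majority_override = majority_override)
  I_bs <- baseline_current(V_bs)
  v_bs <- drift_velocity(V_bs, pore, maj)
  n_bs <- baseline_charge_density(I_bs, v_bs, pore)
  C_EDL <- edl_capacitance(solution, pore, method = cedl_method,
                           majority_override = majority_override)
  structure(list(V_bs = V_bs, I_bs = I_bs, E = V_bs / pore$L_Au,
                 v_bs = v_bs, n_bs = n_bs, C_EDL = C_EDL,
                 majority = maj, pore = pore, solution = solution),
            class = "baseline_state")
}

#' @export
print.baseline_state <- function(x, ...) {
  cat(sprintf(
    "<baseline_state> V_bs = %.3g mV, I_bs = %.3g nA, n_bs = %.3g C/m^3, C_EDL = %.3g F\n",
    x$V_bs * 1e3, x$I_bs * 1e9, x$n_bs, x$C_EDL))
  invisible(x)
}

#' Baseline concentration sweep
#'
#' Baseline predictions across a total-concentration sweep of one
#' electrolyte composition, returned as a tidy table in instrument units (mV, nA).
#'
#' @param solution An [electrolyte()] giving the composition ratios.
#' @param pore A [nanopore()].
#' @param conc_M Vector of total ion concentrations, mol/L. The default is
#'   the standard seven-decade sweep (each ion at 1e-7..1e-1 M for a binary
#'   electrolyte).
#' @param majority_override Optional majority-ion override name.
#' @return A tibble with columns `conc_M` (per-species scale, mol/L),
#'   `V_bs_mV`, `I_bs_nA`, `n_bs_C_m3`, `C_EDL_F`.
#' @export
#' @examples
#' baseline_sweep(electrolyte(Na = 1, F = 1), nanopore(2.3))
baseline_sweep <- function(solution, pore,
                           conc_M = 10^seq(-7, -1, by = 1),
                           majority_override = NULL) {
  stopifnot(inherits(solution, "electrolyte"))
  n_sp <- nrow(solution$species)
  C_EDL <- edl_capacitance(solution, pore,
                           majority_override = majority_override)
  out <- purrr::map_dfr(conc_M, function(cc) {
    sol <- rescale_electrolyte(solution, cc * n_sp)
    maj <- suppressMessages(majority_ion(sol, override = majority_override))
    V <- predict_Vbs(sol, pore, majority_override = majority_override)
    I <- baseline_current(V)
    v <- drift_velocity(V, pore, maj)
    tibble::tibble(
      conc_M = cc,
      V_bs_mV = V * 1e3,
      I_bs_nA = I * 1e9,
      n_bs_C_m3 = baseline_charge_density(I, v, pore),
      C_EDL_F = C_EDL
    )
  })
  class(out) <- c("baseline_sweep", class(out))
  out
}
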