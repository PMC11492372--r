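# Physical constants (SI, CODATA) and the model's calibration constants.
# Every empirical coefficient of the signal model lives here, in one place.

.k_B <- 1.380649e-23      # Boltzmann constant, J/K
.e_charge <- 1.602176634e-19  # elementary charge, C
.N_Av <- 6.02214076e23    # Avogadro number, 1/mol
.R_gas <- 8.31446261815324    # gas constant, J/K/mol
.Faraday <- 96485.33212   # Faraday constant, C/mol
.eps0 <- 8.8541878128e-12 # vacuum permittivity, F/m
.eps_r_water <- 78.41     # relative permittivity of water near 298 K

#' Model constants
#'
#' Returns the calibration constants of the empirical nanopore signal model.
#' These are device-level constants, not universal physics: the baseline
#' current line (`G_pore`, `I0_pore`) describes the linear current-potential
#' response of a metal-layered nanopore device, and `screening` sets the
#' degree of electrostatic compensation by the electrolyte around a charged
#' analyte (values above 1 correspond to mild EDL overscreening).
#'
#' @return A named list:
#' \describe{
#'   \item{G_pore}{slope of the baseline current-potential line, A/V.}
#'   \item{I0_pore}{intercept of the baseline current-potential line, A.}
#'   \item{screening}{electrostatic compensation factor (dimensionless).}
#'   \item{L_C}{characteristic length scale used by the partition
#'     coefficient, m (1 nm).}
#'   \item{I_supp}{metal-layer supply current, A. Metadata only; it does not
#'     enter any computation.}
#' }
#' @export
#' @examples
#' model_constants()$G_pore
model_constants <- function() {
  list(
    G_pore = 1.75e-8,   # A/V; ~17.5 nS device transconductance
    I0_pore = 7.0e-11,  # A; small enough that sign(I_bs) == sign(V_bs)
                        # over 1e-7..1e-1 M and r_np up to 4 nm
    screening = 1.15,   # overscreening: compensation overshoots by 15%
    L_C = 1e-9,         # m
    I_supp = 37.4e-12   # A (metadata)
  )
}
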