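#' In-pore mobility from one translocation event
#'
#' Rearranged drift relation with `E = V_bs / L_Au` and `v = L / t_ic`:
#' `mu = L * L_Au / (|V_bs| * t_ic)`. Reported as a magnitude; the event
#' polarity is carried separately by the signal tables.
#'
#' @param t_ic Translocation time, s (> 0). Vectorised.
#' @param V_bs Baseline EDL potential, V (non-zero).
#' @param pore A [nanopore()].
#' @return Mobility, m^2/V/s.
#' @export
#' @examples
#' mobility_from_event(1e-3, -50e-3, nanopore(2.3))
mobility_from_event <- function(t_ic, V_bs, pore) {
  stopifnot(inherits(pore, "nanopore"))
  if (any(t_ic <= 0)) stop("t_ic must be positive", call. = FALSE)
  if (any(V_bs == 0)) stop("degenerate field: V_bs = 0", call. = FALSE)
  pore$L * pore$L_Au / (abs(V_bs) * t_ic)
}

#' Diffusivity from mobility (Stokes-Einstein)
#'
#' Einstein relation for a carrier of valence `z`:
#' `D = mu * k_B * T / (|z| * e)`. Linear in temperature; undefined for a
#' neutral analyte.
#'
#' @param mobility Mobility, m^2/V/s (> 0). Vectorised.
#' @param valence Signed integer valence (non-zero); only |z| enters.
#' @param temperature Temperature, K.
#' @return Diffusion coefficient, m^2/s.
#' @export
diffusivity_from_mobility <- function(mobility, valence, temperature = 298) {
  if (any(mobility <= 0)) stop("mobility must be positive", call. = FALSE)
  if (any(valence == 0))
    stop("diffusivity undefined for a neutral analyte (z = 0)", call. = FALSE)
  if (any(temperature <= 0)) stop("temperature must be positive", call. = FALSE)
  mobility * .k_B * temperature / (abs(valence) * .e_charge)
}

#' Per-event kinetic estimates from an event table
#'
#' @param events A data frame with a `t_ic_ms` column (instrument units) and
#'   optionally `condition`.
#' @param pore A [nanopore()].
#' @param V_bs Baseline EDL potential, V, recycled across events.
#' @param valence Analyte valence used for the diffusivity.
#' @param temperature Temperature, K.
#' @return The input tibble with `mobility_m2_Vs` and `diffusivity_m2_s`
#'   columns appended.
#' @export
kinetics <- function(events, pore, V_bs, valence, temperature = 298) {
  stopifnot(is.data.frame(events), "t_ic_ms" %in% names(events))
  ev <- tibble::as_tibble(events)
  mu <- mobility_from_event(ev$t_ic_ms * 1e-3, V_bs, pore)
  ev$mobility_m2_Vs <- mu
  ev$diffusivity_m2_s <- diffusivity_from_mobility(mu, valence, temperature)
  ev
}

#' Summarise kinetic estimates per condition
#'
#' Mean and standard deviation of mobility and diffusivity across events,
#' grouped by `condition` when present.
#'
#' @param kin Output of [kinetics()].
#' @return A tibble with one row per condition.
#' @export
summarize_kinetics <- function(kin) {
  g <- if ("condition" %in% names(kin)) dplyr::group_by(kin, .data$condition)
       else kin
  dplyr::summarise(
    g,
    n_events = dplyr::n(),
    mobility_mean = mean(.data$mobility_m2_Vs),
    mobility_sd = stats::sd(.data$mobility_m2_Vs),
    diffusivity_mean = mean(.data$diffusivity_m2_s),
    diffusivity_sd = stats::sd(.data$diffusivity_m2_s),
    .groups = "drop"
  )
}

#' Reference bulk mobilities and diffusivities
#'
#' Order-of-magnitude literature values for small ions and molecules in
#' unconfined aqueous solution, used to contrast the strongly reduced in-pore
#' estimates. Configurable by the caller.
#'
#' @return A named list with `mobility` (m^2/V/s) and `diffusivity` (m^2/s).
#' @export
bulk_reference <- function() {
  list(mobility = 5e-8, diffusivity = 1e-9)
}
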