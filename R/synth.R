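#' Simulate a measured event table
#'
#' Draws translocation events from the forward model plus i.i.d. Gaussian
#' noise: each event's `I_ps` and `V_ps` are the model predictions perturbed
#' by zero-mean Gaussian noise with relative standard deviation `noise_rel`,
#' and translocation times are log-normal around `t_ic_ms`. This is the
#' package's stand-in for experimental event tables (no public deposition of
#' the measured traces exists); it emulates event-to-event measurement
#' scatter, not baseline drift or pore-to-pore variability.
#'
#' @param solution An [electrolyte()].
#' @param pore A [nanopore()].
#' @param analyte An [analyte()] giving the true (generating) parameters.
#' @param n_events Number of events.
#' @param t_ic_ms Median translocation time, ms.
#' @param t_ic_spread Log-normal sdlog of the translocation times.
#' @param noise_rel Relative SD of the Gaussian signal noise (0 = noiseless).
#' @param condition Optional condition label column value.
#' @param seed Optional integer seed (local RNG; the global stream is left
#'   untouched).
#' @param baseline Optional precomputed [baseline_state()].
#' @return A tibble with columns `condition` (if given), `V_ps_mV`,
#'   `I_ps_nA`, `t_ic_ms`.
#' @export
#' @examples
#' sol <- electrolyte(Na = 1e-3, F = 1e-3)
#' simulate_events(sol, nanopore(2.3), analyte("ceria", 0.92, 28),
#'                 n_events = 5, seed = 1)
simulate_events <- function(solution, pore, analyte, n_events = 50,
                            t_ic_ms = 1, t_ic_spread = 0.2, noise_rel = 0.05,
                            condition = NULL, seed = NULL, baseline = NULL) {
  stopifnot(n_events >= 1, noise_rel >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  if (is.null(baseline)) baseline <- baseline_state(solution, pore)
  t_ic <- stats::rlnorm(n_events, meanlog = log(t_ic_ms * 1e-3),
                        sdlog = t_ic_spread)
  base <- predict_signals(solution, pore, analyte, t_ic = mean(t_ic),
                          baseline = baseline)
  I <- base$I_ps_A * (1 + stats::rnorm(n_events, 0, noise_rel))
  V <- base$V_ps_V * (1 + stats::rnorm(n_events, 0, noise_rel))
  out <- tibble::tibble(V_ps_mV = V * 1e3, I_ps_nA = I * 1e9,
                        t_ic_ms = t_ic * 1e3)
  if (!is.null(condition)) out <- dplyr::mutate(out, condition = condition,
                                                .before = 1)
  out
}

#' Simulate an oxidation/reduction titration series
#'
#' Generates event tables for a sequence of conditions with prescribed true
#' radii and charges (e.g. a ceria nanoparticle series titrated with an
#' oxidant, where the particle charge grows), ready for [fit_series()].
#'
#' @param solution,pore As in [simulate_events()].
#' @param true_r_nm,true_z Vectors (same length) of generating radii (nm)
#'   and charges per condition.
#' @param conditions Condition labels (default `"c1"`, `"c2"`, ...).
#' @param use_stokes Passed to [analyte()].
#' @param n_events,noise_rel,t_ic_ms,seed As in [simulate_events()].
#' @return A stacked event tibble with a `condition` column.
#' @export
simulate_series <- function(solution, pore, true_r_nm, true_z,
                            conditions = NULL, use_stokes = TRUE,
                            n_events = 50, noise_rel = 0.05, t_ic_ms = 1,
                            seed = NULL) {
  stopifnot(length(true_r_nm) == length(true_z))
  if (is.null(conditions)) conditions <- paste0("c", seq_along(true_z))
  baseline <- baseline_state(solution, pore)
  purrr::map_dfr(seq_along(true_z), function(i) {
    simulate_events(solution, pore,
                    analyte(conditions[i], true_r_nm[i], true_z[i],
                            use_stokes = use_stokes),
                    n_events = n_events, noise_rel = noise_rel,
                    t_ic_ms = t_ic_ms, condition = conditions[i],
                    seed = if (is.null(seed)) NULL else seed + i,
                    baseline = baseline)
  })
}

#' Read / write event tables
#'
#' Event CSVs use the measurement units of the instrument: columns
#' `condition` (optional), `V_ps_mV`, `I_ps_nA`, `t_ic_ms`.
#'
#' @param path File path.
#' @return `read_events()` returns a tibble.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("V_ps_mV", "I_ps_nA")
  if (!all(need %in% names(df)))
    stop("event table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tibble::as_tibble(df)
}

#' @rdname read_events
#' @param events Event tibble.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
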