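# Synthetic current traces and FDHM event extraction.

#' Simulate a raw current trace
#'
#' Generates a uniformly sampled ionic-current trace at the baseline level
#' predicted for the solution and pore, injects translocation spikes of
#' amplitude `I_ps` (triangular, with FDHM equal to the drawn translocation
#' time) and adds white Gaussian noise. Event centres are spread evenly over
#' the trace with a small jitter so events do not overlap at the default
#' rates. Fully reproducible from `seed`.
#'
#' @param solution An [electrolyte()].
#' @param pore A [nanopore()].
#' @param analyte An [analyte()].
#' @param event_rate Mean event rate, 1/s.
#' @param duration Trace duration, s.
#' @param noise_sd Noise standard deviation, A.
#' @param t_ic_ms Median FDHM of the injected spikes, ms.
#' @param t_ic_spread Log-normal sdlog of the spike FDHMs.
#' @param sample_rate Sampling rate, Hz (default 80 000).
#' @param seed Optional integer seed.
#' @return A tibble of class `"current_trace"` with columns `time_s`,
#'   `current_A`; attributes `sample_rate`, `baseline_A` and `truth` (the
#'   injected ground-truth event table).
#' @export
#' @examples
#' sol <- electrolyte(Na = 1e-3, F = 1e-3)
#' tr <- simulate_trace(sol, nanopore(2.3), analyte("ceria", 1.27, 112,
#'                      use_stokes = FALSE), event_rate = 5, duration = 0.5,
#'                      noise_sd = 2e-11, seed = 1)
simulate_trace <- function(solution, pore, analyte, event_rate = 5,
                           duration = 1, noise_sd = 0, t_ic_ms = 1,
                           t_ic_spread = 0.1, sample_rate = 80000,
                           seed = NULL) {
  stopifnot(duration > 0, sample_rate > 0, event_rate >= 0, noise_sd >= 0)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  bs <- baseline_state(solution, pore)
  n <- floor(duration * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  current <- rep(bs$I_bs, n)

  n_ev <- round(event_rate * duration)
  truth <- tibble::tibble(center_s = numeric(0), amplitude_A = numeric(0),
                          t_ic_s = numeric(0))
  if (n_ev > 0) {
    sig <- predict_signals(solution, pore, analyte, t_ic = t_ic_ms * 1e-3,
                           baseline = bs)
    spacing <- duration / n_ev
    centers <- (seq_len(n_ev) - 0.5) * spacing +
      stats::runif(n_ev, -0.1, 0.1) * spacing
    fdhm <- stats::rlnorm(n_ev, log(t_ic_ms * 1e-3), t_ic_spread)
    for (i in seq_len(n_ev)) {
      half_base <- fdhm[i]  # triangle: FDHM = half the base
      shape <- pmax(0, 1 - abs(tt - centers[i]) / half_base)
      current <- current + sig$I_ps_A * shape
    }
    truth <- tibble::tibble(center_s = centers, amplitude_A = sig$I_ps_A,
                            t_ic_s = fdhm)
  }
  if (noise_sd > 0) current <- current + stats::rnorm(n, 0, noise_sd)

  out <- tibble::tibble(time_s = tt, current_A = current)
  class(out) <- c("current_trace", class(out))
  attr(out, "sample_rate") <- sample_rate
  attr(out, "baseline_A") <- bs$I_bs
  attr(out, "truth") <- truth
  out
}

#' Extract translocation events from a current trace (FDHM)
#'
#' Estimates the local baseline with a rolling median, flags excursions
#' beyond `threshold_sd` robust standard deviations (MAD) of the residual,
#' and measures each event's full duration at half-maximum with linear
#' interpolation at the half-maximum crossings. Event polarity is
#' auto-detected per trace from the dominant excursion direction. Extraction
#' is invariant under baseline shifts and amplitude scaling, and under time
#' reversal for symmetric pulses.
#'
#' @param trace A `current_trace`, or any data frame with `time_s` and
#'   `current_A` columns (at least 100 samples).
#' @param threshold_sd Detection threshold in robust SDs.
#' @param baseline_window Rolling-median window, samples (odd; clipped to the
#'   trace length).
#' @return A tibble with one row per event, in time order: `onset_s`,
#'   `peak_time_s`, `peak_amplitude_A` (signed, baseline-subtracted),
#'   `t_ic_s`, `t_ic_ms`, `baseline_local_A`.
#' @export
extract_events <- function(trace, threshold_sd = 5, baseline_window = 1001) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "current_A") %in% names(trace)))
  n <- nrow(trace)
  if (n < 100) stop("trace too short (< 100 samples)", call. = FALSE)
  y <- trace$current_A
  tt <- trace$time_s
  if (any(!is.finite(y))) stop("trace contains non-finite samples", call. = FALSE)

  k <- min(baseline_window, if (n %% 2 == 1) n else n - 1)
  if (k %% 2 == 0) k <- k - 1
  base <- stats::runmed(y, k, endrule = "median")
  dev <- y - base
  s <- stats::mad(dev)
  if (s == 0) s <- stats::sd(dev)
  if (!is.finite(s) || s == 0)
    stop("no baseline estimable from this trace", call. = FALSE)

  hit0 <- abs(dev) > threshold_sd * s
  if (mean(hit0) > 0.5)
    stop("no baseline estimable: most of the trace is excursion", call. = FALSE)
  if (!any(hit0)) return(tibble::tibble(
    onset_s = numeric(0), peak_time_s = numeric(0),
    peak_amplitude_A = numeric(0), t_ic_s = numeric(0), t_ic_ms = numeric(0),
    baseline_local_A = numeric(0)
  ))

  polarity <- sign(sum(dev[hit0]))
  # short boxcar smoothing suppresses noise-induced run splitting; it leaves
  # the half-maximum crossings of triangular and rectangular pulses exact
  d <- polarity * as.numeric(stats::filter(dev, rep(1 / 5, 5), sides = 2))
  d[is.na(d)] <- 0
  hit <- d > threshold_sd * s

  # contiguous runs of threshold crossings
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], ends[r$values])

  dt <- stats::median(diff(tt))
  half_crossing <- function(i_in, i_out, half) {
    # linear interpolation of the time where d crosses `half`
    # between the sample inside (above) and outside (below)
    if (i_out < 1 || i_out > n) return(tt[i_in])
    frac <- (d[i_in] - half) / (d[i_in] - d[i_out])
    tt[i_in] + frac * (tt[i_out] - tt[i_in])
  }

  # walk outward from the peak to the last sample at or above the half-max,
  # tolerating up to `lag` consecutive noise dips below it
  walk_out <- function(p, half, dir, lag = 3) {
    i <- p
    below <- 0
    j <- p + dir
    while (j >= 1 && j <= n && below < lag) {
      if (d[j] >= half) {
        i <- j
        below <- 0
      } else below <- below + 1
      j <- j + dir
    }
    i
  }

  out <- purrr::map_dfr(seq_len(nrow(runs)), function(j) {
    a <- runs[j, 1]; b <- runs[j, 2]
    p <- a + which.max(d[a:b]) - 1
    peak <- polarity * dev[p]  # unsmoothed amplitude at the detected peak
    if (peak <= 0) return(NULL)
    half <- peak / 2
    i <- walk_out(p, half, -1L)
    t_left <- half_crossing(i, i - 1, half)
    i <- walk_out(p, half, +1L)
    t_right <- half_crossing(i, i + 1, half)
    fdhm <- t_right - t_left
    if (!is.finite(fdhm) || fdhm <= 0) fdhm <- dt
    tibble::tibble(
      onset_s = t_left,
      peak_time_s = tt[p],
      peak_amplitude_A = polarity * peak,
      t_ic_s = fdhm,
      t_ic_ms = fdhm * 1e3,
      baseline_local_A = base[p]
    )
  })
  out <- dplyr::arrange(out, .data$onset_s)
  if (nrow(out) > 1) {
    # runs that walked out to overlapping half-max windows are one event;
    # keep the larger peak
    keep <- rep(TRUE, nrow(out))
    last <- 1
    for (i in 2:nrow(out)) {
      if (out$onset_s[i] < out$onset_s[last] + out$t_ic_s[last]) {
        if (abs(out$peak_amplitude_A[i]) > abs(out$peak_amplitude_A[last])) {
          keep[last] <- FALSE
          last <- i
        } else keep[i] <- FALSE
      } else last <- i
    }
    out <- out[keep, ]
  }
  out
}

#' Write / read a trace as two-column CSV
#'
#' @param trace A `current_trace` (or compatible data frame).
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace[, c("time_s", "current_A")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  class(df) <- c("current_trace", class(df))
  attr(df, "sample_rate") <- 1 / stats::median(diff(df$time_s))
  df
}
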