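# Canonical hemodynamic response function and event-regressor construction.

#' Canonical double-gamma HRF
#'
#' The standard difference-of-gammas: a positive lobe with peak delay 6 s and
#' an undershoot with delay 16 s (dispersions 1), undershoot ratio 1/6, on a
#' 32 s support. The kernel is normalized to peak amplitude 1, so a unit-event
#' beta is on the scale of the underlying event amplitude.
#'
#' @param dt_s Sampling interval in seconds.
#' @param duration_s Kernel support in seconds (default 32).
#' @return Numeric vector: HRF sampled at `0, dt, 2 dt, ...`.
#' @export
canonical_hrf <- function(dt_s, duration_s = 32) {
  stopifnot(dt_s > 0)
  t <- seq(0, duration_s, by = dt_s)
  hrf_eval(t)
}

# Analytic double-gamma, peak-normalized; vectorized over t (seconds).
# Peak value of dgamma(t, 6, 1) - dgamma(t, 16, 1)/6 located near t = 5.0 s.
hrf_raw <- function(t) {
  ifelse(t <= 0, 0, stats::dgamma(t, shape = 6, rate = 1) -
           stats::dgamma(t, shape = 16, rate = 1) / 6)
}

.hrf_cache <- new.env(parent = emptyenv())

hrf_peak_value <- function() {
  if (is.null(.hrf_cache$peak)) {
    .hrf_cache$peak <- max(hrf_raw(seq(0, 32, by = 0.001)))
  }
  .hrf_cache$peak
}

hrf_eval <- function(t_s) {
  out <- hrf_raw(t_s) / hrf_peak_value()
  out[t_s > 32] <- 0   # canonical kernel support ends at 32 s
  out
}

#' Event regressor: duration-0 impulses convolved with the canonical HRF
#'
#' Evaluates the superposition of canonical HRFs at the volume acquisition
#' times, one HRF per event onset (events modeled with duration 0).
#'
#' @param onsets_s Event onsets in seconds (run clock).
#' @param times_s Volume acquisition times in seconds.
#' @return Numeric vector of regressor values at `times_s`.
#' @export
hrf_regressor <- function(onsets_s, times_s) {
  if (length(onsets_s) == 0) return(numeric(length(times_s)))
  lags <- outer(times_s, onsets_s, "-")
  v <- hrf_eval(pmin(pmax(lags, -1), 40))
  rowSums(v)
}
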