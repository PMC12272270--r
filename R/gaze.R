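# Gaze trace synthesis: distance-driven scan paths over a search display,
# sampled at 500 Hz, with item-type-specific dwell durations and minimum-jerk
# saccade profiles guaranteed to exceed the saccade detector's thresholds.

#' Gaze simulation parameters
#'
#' Defaults reproduce, in expectation, the empirical mean fixation durations
#' per item type (targets 465 ms, rare distractors 430 ms, common distractors
#' 368 ms) and a 500 Hz sampling rate. Dwell durations are drawn from a normal
#' distribution truncated below at `min_fixdur_ms`. Saccade durations follow a
#' main-sequence-like model: peak velocity `vpeak_base + vpeak_slope * amplitude`
#' with a minimum-jerk position profile, which keeps peak velocity and
#' acceleration far above the 30 deg/s and 9500 deg/s^2 detection thresholds.
#'
#' @param sample_rate_hz Sampling rate in Hz.
#' @param fixdur_mean_ms,fixdur_sd_ms Named numeric vectors (`T`, `RD`, `CD`),
#'   dwell duration mean and SD in ms.
#' @param min_fixdur_ms Lower truncation bound for dwell durations, ms.
#' @param refix_prob Probability that an item visit is split in two by a small
#'   within-item saccade (immediate refixation).
#' @param refix_offset_deg Amplitude of the within-item refixation saccade.
#' @param pos_noise_sd_deg Gaussian positional noise SD during fixation, deg.
#' @param initial_latency_ms Dwell at display center before the first saccade.
#' @param motor_latency_ms Manual response latency after the last fixation.
#' @param vpeak_base,vpeak_slope Saccade peak-velocity model, deg/s and
#'   deg/s per deg of amplitude.
#' @param min_saccade_ms Minimum saccade duration, ms.
#' @return List of class `fixfmri_gaze_params`.
#' @export
gaze_params <- function(sample_rate_hz = 500,
                        fixdur_mean_ms = c(T = 465, RD = 430, CD = 368),
                        fixdur_sd_ms = c(T = 120, RD = 123, CD = 77),
                        min_fixdur_ms = 100,
                        refix_prob = 0.1,
                        refix_offset_deg = 0.4,
                        pos_noise_sd_deg = 0.02,
                        initial_latency_ms = 200,
                        motor_latency_ms = 300,
                        vpeak_base = 150,
                        vpeak_slope = 30,
                        min_saccade_ms = 8) {
  p <- list(sample_rate_hz = sample_rate_hz, fixdur_mean_ms = fixdur_mean_ms,
            fixdur_sd_ms = fixdur_sd_ms, min_fixdur_ms = min_fixdur_ms,
            refix_prob = refix_prob, refix_offset_deg = refix_offset_deg,
            pos_noise_sd_deg = pos_noise_sd_deg,
            initial_latency_ms = initial_latency_ms,
            motor_latency_ms = motor_latency_ms,
            vpeak_base = vpeak_base, vpeak_slope = vpeak_slope,
            min_saccade_ms = min_saccade_ms)
  stopifnot(all(p$fixdur_mean_ms > 0), all(p$fixdur_sd_ms >= 0),
            p$min_fixdur_ms > 0, p$refix_prob >= 0, p$refix_prob <= 1,
            p$sample_rate_hz > 0)
  # The saccade model must yield peak velocities comfortably above the 30 deg/s
  # detection threshold for the smallest saccades it can produce.
  amp_min <- min(p$refix_offset_deg, DISPLAY_MIN_DIST_DEG)
  dur_s <- saccade_duration_ms(amp_min, p) / 1000
  if (amp_min / dur_s < 30) {
    stop("saccade model cannot exceed the 30 deg/s detection threshold ",
         "for amplitude ", amp_min, " deg", call. = FALSE)
  }
  structure(p, class = "fixfmri_gaze_params")
}

# Saccade duration from the peak-velocity model, rounded up to an even number
# of samples (>= min_saccade_ms). Minimum-jerk peak velocity is 1.875 * D / T.
saccade_duration_ms <- function(amplitude_deg, params) {
  vpeak <- params$vpeak_base + params$vpeak_slope * amplitude_deg
  dt <- 1000 / params$sample_rate_hz
  dur <- 1000 * 1.875 * amplitude_deg / vpeak
  dur <- max(dur, params$min_saccade_ms)
  ceiling(dur / dt) * dt
}

# Minimum-jerk displacement fraction at normalized time tau in [0, 1].
minjerk_s <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

# Truncated-normal dwell duration (ms), rounded to the sample grid.
draw_dwell_ms <- function(type, params) {
  m <- params$fixdur_mean_ms[[type]]
  s <- params$fixdur_sd_ms[[type]]
  dt <- 1000 / params$sample_rate_hz
  repeat {
    d <- stats::rnorm(1, m, s)
    if (d >= params$min_fixdur_ms) break
  }
  max(round(d / dt), 1) * dt
}

# Scan-path order: nearest unvisited item from the current position, ties by
# lowest item id, starting at the display center. Catch trials (2 targets)
# self-terminate at the visit of the second target.
scan_path_order <- function(display) {
  it <- display$items
  n_targets <- condition_counts(display$condition)[["n_target"]]
  remaining <- seq_len(nrow(it))
  pos <- c(0, 0)
  order <- integer(0)
  targets_seen <- 0L
  while (length(remaining) > 0) {
    d <- sqrt((it$x[remaining] - pos[1])^2 + (it$y[remaining] - pos[2])^2)
    pick <- remaining[which.min(d)]  # which.min takes the first (lowest id) on ties
    order <- c(order, pick)
    pos <- c(it$x[pick], it$y[pick])
    remaining <- setdiff(remaining, pick)
    if (it$type[pick] == "T") {
      targets_seen <- targets_seen + 1L
      if (n_targets >= 2L && targets_seen >= 2L) break
    }
  }
  order
}

#' Simulate a gaze trace for one trial
#'
#' Builds a distance-driven scan path over the trial's display (nearest
#' unvisited item next; catch trials stop at the second target), draws dwell
#' durations per item type, inserts minimum-jerk saccades between items, adds
#' Gaussian positional noise during fixation, and samples the whole trajectory
#' on a uniform 2 ms grid. The returned ground-truth log records every item
#' visit and every saccade for oracle testing.
#'
#' @param display A `fixfmri_display`.
#' @param params A [gaze_params()] object.
#' @param rng_seed Optional integer seed.
#' @param trace If `FALSE`, skip synthesizing the 500 Hz sample trace and
#'   return only the ground-truth logs (fast path for large simulation
#'   studies that bypass the oculomotor parser).
#' @return List of class `fixfmri_gaze` with elements `trace` (data.frame
#'   `time_ms`, `x_deg`, `y_deg`, or `NULL`), `fixations` (ground-truth item
#'   visits: `item_id`, `item_type`, `onset_ms`, `duration_ms`,
#'   `n_segments`), `saccades` (`onset_ms`, `duration_ms`, `amplitude_deg`)
#'   and `initial_latency_ms`.
#' @export
simulate_gaze <- function(display, params = gaze_params(), rng_seed = NULL,
                          trace = TRUE) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  dt <- 1000 / params$sample_rate_hz
  it <- display$items
  order <- scan_path_order(display)
  n_it <- length(order)

  seg_x <- list(); seg_y <- list()
  fx_id <- integer(n_it); fx_type <- character(n_it); fx_on <- numeric(n_it)
  fx_dur <- numeric(n_it); fx_nseg <- integer(n_it)
  sc_on <- numeric(0); sc_dur <- numeric(0); sc_amp <- numeric(0)
  t_cursor <- 0

  emit_fixation <- function(pos, n_samples) {
    if (!trace) return(invisible())
    seg_x[[length(seg_x) + 1]] <<- pos[1] +
      stats::rnorm(n_samples, 0, params$pos_noise_sd_deg)
    seg_y[[length(seg_y) + 1]] <<- pos[2] +
      stats::rnorm(n_samples, 0, params$pos_noise_sd_deg)
  }
  emit_saccade <- function(p0, p1) {
    amp <- sqrt(sum((p1 - p0)^2))
    dur <- saccade_duration_ms(amp, params)
    if (trace) {
      m <- as.integer(round(dur / dt))
      s <- minjerk_s(seq_len(m) / (m + 1))
      seg_x[[length(seg_x) + 1]] <<- p0[1] + (p1[1] - p0[1]) * s
      seg_y[[length(seg_y) + 1]] <<- p0[2] + (p1[2] - p0[2]) * s
    }
    sc_on <<- c(sc_on, t_cursor); sc_dur <<- c(sc_dur, dur)
    sc_amp <<- c(sc_amp, amp)
    t_cursor <<- t_cursor + dur
  }

  # Initial central fixation (latency before the first saccade).
  lat_samples <- max(1L, as.integer(round(params$initial_latency_ms / dt)))
  latency_ms <- lat_samples * dt
  emit_fixation(c(0, 0), lat_samples)
  t_cursor <- latency_ms
  pos <- c(0, 0)

  for (k in seq_len(n_it)) {
    idx <- order[k]
    target_pos <- c(it$x[idx], it$y[idx])
    emit_saccade(pos, target_pos)
    dwell <- draw_dwell_ms(it$type[idx], params)
    onset <- t_cursor
    refix <- stats::runif(1) < params$refix_prob
    if (refix && dwell >= 2 * params$min_fixdur_ms) {
      frac <- stats::runif(1, 0.4, 0.6)
      d1 <- max(1, round(frac * dwell / dt)) * dt
      d2 <- dwell - d1
      ang <- stats::runif(1, 0, 2 * pi)
      off <- target_pos + params$refix_offset_deg * c(cos(ang), sin(ang))
      emit_fixation(target_pos, as.integer(d1 / dt)); t_cursor <- t_cursor + d1
      emit_saccade(target_pos, off)
      emit_fixation(off, as.integer(d2 / dt)); t_cursor <- t_cursor + d2
      pos <- off
      n_seg <- 2L
    } else {
      emit_fixation(target_pos, as.integer(dwell / dt)); t_cursor <- t_cursor + dwell
      pos <- target_pos
      n_seg <- 1L
    }
    fx_id[k] <- idx; fx_type[k] <- it$type[idx]; fx_on[k] <- onset
    fx_dur[k] <- dwell; fx_nseg[k] <- n_seg
  }

  tr <- NULL
  if (trace) {
    x <- unlist(seg_x); y <- unlist(seg_y)
    tr <- data.frame(time_ms = (seq_along(x) - 1) * dt, x_deg = x, y_deg = y)
  }
  structure(list(trace = tr,
                 fixations = data.frame(item_id = fx_id, item_type = fx_type,
                                        onset_ms = fx_on, duration_ms = fx_dur,
                                        n_segments = fx_nseg,
                                        stringsAsFactors = FALSE),
                 saccades = data.frame(onset_ms = sc_on, duration_ms = sc_dur,
                                       amplitude_deg = sc_amp),
                 initial_latency_ms = latency_ms),
            class = "fixfmri_gaze")
}

#' Simulate the manual response for one trial
#'
#' Each target present in the display is independently missed with probability
#' `miss_prob`; the reported count is the number of detected targets (the task
#' is a three-alternative 0/1/2 count). Response time is the offset of the last
#' fixation plus a constant motor latency.
#'
#' @param display A `fixfmri_display`.
#' @param gaze A `fixfmri_gaze` for the same trial (for response timing).
#' @param miss_prob Per-target miss probability in `[0, 1]`.
#' @param params A [gaze_params()] (motor latency).
#' @param rng_seed Optional integer seed.
#' @return data.frame with `response`, `rt_ms`, `correct`, `technical_error`.
#' @export
simulate_response <- function(display, gaze, miss_prob = 0.0816,
                              params = gaze_params(), rng_seed = NULL) {
  stopifnot(miss_prob >= 0, miss_prob <= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n_targets <- condition_counts(display$condition)[["n_target"]]
  detected <- if (n_targets > 0) sum(stats::runif(n_targets) >= miss_prob) else 0L
  fx <- gaze$fixations
  last_off <- if (nrow(fx) > 0) max(fx$onset_ms + fx$duration_ms) else
    gaze$initial_latency_ms
  data.frame(response = as.integer(detected),
             rt_ms = last_off + params$motor_latency_ms,
             correct = detected == n_targets,
             technical_error = FALSE)
}
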