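# Saccade/fixation parsing of raw gaze traces: velocity + acceleration
# thresholds, interval complements, nearest-item assignment, refixation
# collapsing, and fixation ranks.

#' Oculomotor detection parameters
#'
#' Saccades are detected where gaze speed exceeds `velocity_threshold`
#' (30 deg/s) and the excursion's peak acceleration reaches
#' `acceleration_threshold` (9500 deg/s^2). Velocity is estimated by central
#' differences over a 5-sample window; candidate excursions shorter than
#' `min_duration_samples` are discarded as noise spikes.
#'
#' @param velocity_threshold_dps Speed threshold, deg/s.
#' @param acceleration_threshold_dps2 Peak-acceleration threshold, deg/s^2.
#' @param velocity_window_samples Central-difference window (odd, >= 3).
#' @param min_duration_samples Minimum saccade duration in samples.
#' @return List of class `fixfmri_oculo_params`.
#' @export
oculomotor_params <- function(velocity_threshold_dps = 30,
                              acceleration_threshold_dps2 = 9500,
                              velocity_window_samples = 5L,
                              min_duration_samples = 4L) {
  stopifnot(velocity_threshold_dps > 0, acceleration_threshold_dps2 > 0,
            velocity_window_samples >= 3L, velocity_window_samples %% 2L == 1L)
  structure(list(velocity_threshold_dps = velocity_threshold_dps,
                 acceleration_threshold_dps2 = acceleration_threshold_dps2,
                 velocity_window_samples = velocity_window_samples,
                 min_duration_samples = min_duration_samples),
            class = "fixfmri_oculo_params")
}

# Central-difference derivative over a (2h+1)-sample window; edges get the
# nearest interior estimate set to 0 (treated as fixation).
central_diff <- function(v, dt_s, half_window) {
  n <- length(v)
  d <- rep(0, n)
  idx <- (half_window + 1):(n - half_window)
  d[idx] <- (v[idx + half_window] - v[idx - half_window]) / (2 * half_window * dt_s)
  d
}

check_uniform_trace <- function(trace) {
  if (nrow(trace) < 3L) stop("gaze trace too short (< 3 samples)", call. = FALSE)
  dts <- diff(trace$time_ms)
  if (any(abs(dts - dts[1]) > 1e-9)) {
    stop("gaze trace timestamps are not uniform", call. = FALSE)
  }
  dts[1]
}

#' Detect saccades in a gaze trace
#'
#' Maximal contiguous runs of samples whose speed exceeds the velocity
#' threshold become candidate saccades; a candidate is kept if it lasts at
#' least `min_duration_samples` samples and its peak acceleration magnitude
#' reaches the acceleration threshold. All remaining samples belong to
#' fixation periods.
#'
#' @param trace data.frame with `time_ms`, `x_deg`, `y_deg` (uniform sampling).
#' @param params [oculomotor_params()].
#' @return data.frame with `onset_ms`, `offset_ms` (half-open interval),
#'   `amplitude_deg` (Euclidean start-to-end), `peak_velocity_dps`,
#'   `direction_rad` (start-to-end angle, stored but unused downstream).
#' @export
detect_saccades <- function(trace, params = oculomotor_params()) {
  dt_ms <- check_uniform_trace(trace)
  dt_s <- dt_ms / 1000
  h <- (params$velocity_window_samples - 1L) %/% 2L
  vx <- central_diff(trace$x_deg, dt_s, h)
  vy <- central_diff(trace$y_deg, dt_s, h)
  speed <- sqrt(vx^2 + vy^2)
  ax <- central_diff(vx, dt_s, 1L)
  ay <- central_diff(vy, dt_s, 1L)
  accel <- sqrt(ax^2 + ay^2)

  above <- speed > params$velocity_threshold_dps
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= params$min_duration_samples)
  rows <- lapply(keep, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    if (max(accel[i0:i1]) < params$acceleration_threshold_dps2) return(NULL)
    dx <- trace$x_deg[i1] - trace$x_deg[i0]
    dy <- trace$y_deg[i1] - trace$y_deg[i0]
    data.frame(onset_ms = trace$time_ms[i0],
               offset_ms = trace$time_ms[i1] + dt_ms,
               amplitude_deg = sqrt(dx^2 + dy^2),
               peak_velocity_dps = max(speed[i0:i1]),
               direction_rad = atan2(dy, dx))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      amplitude_deg = numeric(0), peak_velocity_dps = numeric(0),
                      direction_rad = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Segment fixations as the complement of the saccade intervals
#'
#' @param trace Uniform gaze trace.
#' @param saccades Output of [detect_saccades()] (sorted, non-overlapping).
#' @return data.frame with `onset_ms`, `offset_ms`, `duration_ms`,
#'   `x_deg`, `y_deg` (mean gaze position over the fixation samples).
#' @export
segment_fixations <- function(trace, saccades) {
  dt_ms <- check_uniform_trace(trace)
  if (nrow(saccades) > 1) {
    if (is.unsorted(saccades$onset_ms)) stop("saccades must be sorted by onset")
    if (any(saccades$onset_ms[-1] < saccades$offset_ms[-nrow(saccades)])) {
      stop("overlapping saccades")
    }
  }
  t0 <- trace$time_ms[1]
  t_end <- trace$time_ms[nrow(trace)] + dt_ms
  bounds <- rbind(c(t0, t0),
                  cbind(saccades$onset_ms, saccades$offset_ms),
                  c(t_end, t_end))
  rows <- list()
  for (i in seq_len(nrow(bounds) - 1)) {
    on <- bounds[i, 2]; off <- bounds[i + 1, 1]
    if (off - on <= 0) next
    sel <- trace$time_ms >= on & trace$time_ms < off
    rows[[length(rows) + 1]] <- data.frame(
      onset_ms = on, offset_ms = off, duration_ms = off - on,
      x_deg = mean(trace$x_deg[sel]), y_deg = mean(trace$y_deg[sel]))
  }
  if (length(rows) == 0) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), x_deg = numeric(0),
                      y_deg = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Assign a fixation to the nearest display item
#'
#' Returns the id of the item minimizing the Euclidean distance to the mean
#' fixation position; ties are broken by the lowest item id.
#'
#' @param x_deg,y_deg Mean fixation position.
#' @param display A `fixfmri_display`.
#' @return Integer item id.
#' @export
assign_item <- function(x_deg, y_deg, display) {
  it <- display$items
  if (nrow(it) == 0) stop("display is empty")
  d2 <- (it$x - x_deg)^2 + (it$y - y_deg)^2
  it$id[which.min(d2)]  # which.min returns first minimum -> lowest id on ties
}

#' Collapse immediate refixations
#'
#' Maximal runs of consecutive fixations assigned to the same item merge into
#' a single collapsed fixation: duration is the sum of member durations, onset
#' and preceding saccade are those of the first member, the following saccade
#' that of the last member, and position the duration-weighted mean.
#'
#' @param fixations data.frame sorted by onset with columns `onset_ms`,
#'   `duration_ms`, `x_deg`, `y_deg`, `item_id`, `item_type`,
#'   `prec_sacc_amp`, `foll_sacc_amp` (amplitudes may be `NA` at trial edges).
#' @return data.frame of collapsed fixations with an `n_collapsed` column.
#' @export
collapse_refixations <- function(fixations) {
  if (nrow(fixations) == 0) return(cbind(fixations, n_collapsed = integer(0)))
  if (is.unsorted(fixations$onset_ms)) stop("fixations must be sorted by onset")
  # new group whenever the assigned item changes between consecutive fixations
  grp <- cumsum(c(TRUE, fixations$item_id[-1] != fixations$item_id[-nrow(fixations)]))
  rows <- lapply(split(seq_len(nrow(fixations)), grp), function(idx) {
    f <- fixations[idx, , drop = FALSE]
    w <- f$duration_ms / sum(f$duration_ms)
    data.frame(onset_ms = f$onset_ms[1],
               duration_ms = sum(f$duration_ms),
               x_deg = sum(w * f$x_deg), y_deg = sum(w * f$y_deg),
               item_id = f$item_id[1], item_type = f$item_type[1],
               prec_sacc_amp = f$prec_sacc_amp[1],
               foll_sacc_amp = f$foll_sacc_amp[nrow(f)],
               n_collapsed = nrow(f), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign fixation ranks
#'
#' Ranks 1..n in onset order; `is_first_fixation_on_item` is `TRUE` only for
#' an item's earliest collapsed fixation within the trial.
#'
#' @param collapsed Output of [collapse_refixations()], sorted by onset.
#' @return Same data.frame with `rank` and `is_first_fixation_on_item`.
#' @export
compute_ranks <- function(collapsed) {
  n <- nrow(collapsed)
  collapsed$rank <- seq_len(n)
  collapsed$is_first_fixation_on_item <- !duplicated(collapsed$item_id)
  collapsed
}

#' Parse one trial's gaze trace into ranked collapsed fixations
#'
#' Runs the full oculomotor chain: saccade detection, fixation segmentation,
#' nearest-item assignment, flanking-saccade bookkeeping, refixation
#' collapsing, and rank computation. Trial-edge fixations have `NA` flanking
#' saccade amplitudes.
#'
#' @param trace Gaze trace data.frame.
#' @param display The trial's `fixfmri_display`.
#' @param params [oculomotor_params()].
#' @param drop_initial_fixation Drop the fixation already in progress at trace
#'   start (the central drift-correction fixation carried over from before
#'   display onset); it is not a search fixation and would otherwise collapse
#'   into the first item visit.
#' @return data.frame of ranked collapsed fixation events.
#' @export
parse_trial <- function(trace, display, params = oculomotor_params(),
                        drop_initial_fixation = TRUE) {
  sacc <- detect_saccades(trace, params)
  fix <- segment_fixations(trace, sacc)
  if (drop_initial_fixation && nrow(fix) > 1 &&
      abs(fix$onset_ms[1] - trace$time_ms[1]) < 1e-9) {
    fix <- fix[-1, , drop = FALSE]
  }
  if (nrow(fix) == 0) return(fix)
  fix$item_id <- vapply(seq_len(nrow(fix)), function(i) {
    assign_item(fix$x_deg[i], fix$y_deg[i], display)
  }, integer(1))
  fix$item_type <- display$items$type[fix$item_id]
  # flanking saccades: a fixation's preceding saccade ends at its onset,
  # its following saccade starts at its offset
  fix$prec_sacc_amp <- vapply(fix$onset_ms, function(on) {
    j <- which(abs(sacc$offset_ms - on) < 1e-9)
    if (length(j)) sacc$amplitude_deg[j[1]] else NA_real_
  }, numeric(1))
  fix$foll_sacc_amp <- vapply(fix$offset_ms, function(off) {
    j <- which(abs(sacc$onset_ms - off) < 1e-9)
    if (length(j)) sacc$amplitude_deg[j[1]] else NA_real_
  }, numeric(1))
  compute_ranks(collapse_refixations(fix[, c("onset_ms", "duration_ms", "x_deg",
                                             "y_deg", "item_id", "item_type",
                                             "prec_sacc_amp", "foll_sacc_amp")]))
}

#' Behavioral and eye-movement descriptive summary
#'
#' Per-condition error rate (all non-technical-error trials), mean response
#' time and mean number of fixations (correct trials only), and per-item-type
#' mean fixation duration and flanking saccade amplitudes (first fixations on
#' items in correct trials of the three matchable conditions). Cells with no
#' eligible trials are `NA`.
#'
#' @param trials data.frame with one row per trial: `run`, `trial`,
#'   `condition`, `response`, `correct`, `technical_error`, `rt_ms`.
#' @param fixations data.frame of collapsed fixation events for all trials,
#'   with `run`, `trial` columns joining to `trials`.
#' @return List with `by_condition` and `by_item_type` data.frames.
#' @export
summarize_behavior <- function(trials, fixations) {
  tr <- trials[!trials$technical_error, , drop = FALSE]
  conds <- search_conditions()
  by_cond <- do.call(rbind, lapply(conds, function(cc) {
    sel <- tr[tr$condition == cc, , drop = FALSE]
    ok <- sel[sel$correct, , drop = FALSE]
    nfix <- if (nrow(ok)) {
      mean(vapply(seq_len(nrow(ok)), function(i) {
        sum(fixations$run == ok$run[i] & fixations$trial == ok$trial[i])
      }, numeric(1)))
    } else NA_real_
    data.frame(condition = cc,
               n_trials = nrow(sel),
               error_rate_pct = if (nrow(sel)) 100 * mean(!sel$correct) else NA_real_,
               mean_rt_s = if (nrow(ok)) mean(ok$rt_ms) / 1000 else NA_real_,
               mean_n_fixations = nfix, stringsAsFactors = FALSE)
  }))
  key <- paste(fixations$run, fixations$trial)
  ok_tr <- tr[tr$correct & tr$condition %in% c("0T_1RD", "1T_0RD", "1T_1RD"), ]
  fx <- fixations[key %in% paste(ok_tr$run, ok_tr$trial) &
                    fixations$is_first_fixation_on_item, , drop = FALSE]
  by_type <- do.call(rbind, lapply(c("T", "RD", "CD"), function(ty) {
    f <- fx[fx$item_type == ty, , drop = FALSE]
    data.frame(item_type = ty, n = nrow(f),
               mean_fixdur_ms = if (nrow(f)) mean(f$duration_ms) else NA_real_,
               mean_prec_sacc_deg = mean(f$prec_sacc_amp, na.rm = TRUE),
               mean_foll_sacc_deg = mean(f$foll_sacc_amp, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  list(by_condition = by_cond, by_item_type = by_type)
}
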