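# Shared fixtures (memoised: expensive objects are built once per test run)
# and independent oracle implementations used across test files.

.fix_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fix_cache[[key]])) .fix_cache[[key]] <- builder()
  .fix_cache[[key]]
}

# A small but complete analyzed subject: 2 runs, reduced grid, full parser
# round trip and searchlight. Used by GLM/MVPA/pipeline tests.
small_subject <- function() {
  memo("small_subject", function() {
    cfg <- pipeline_config(n_runs = 2, dim = c(16, 16, 12),
                           parse_gaze = TRUE, run_mvpa = TRUE)
    simulate_subject(cfg, seed = 101L)
  })
}

# Fixation-level (no trace) 2-run session with trial table, fixations and
# candidates, for matching tests.
fixation_session <- function(seed = 7L, n_runs = 2L) {
  session <- generate_session(seed, n_runs = n_runs)
  set.seed(seed + 1L)
  trials <- session$trials
  fix <- list()
  beh <- list()
  for (i in seq_len(nrow(trials))) {
    g <- simulate_gaze(session$displays[[i]], rng_seed = seed + i, trace = FALSE)
    b <- simulate_response(session$displays[[i]], g, rng_seed = seed + 1000 + i)
    f <- g$fixations
    out <- data.frame(onset_ms = f$onset_ms, duration_ms = f$duration_ms,
                      x_deg = NA_real_, y_deg = NA_real_, item_id = f$item_id,
                      item_type = f$item_type, prec_sacc_amp = NA_real_,
                      foll_sacc_amp = NA_real_, n_collapsed = f$n_segments)
    out <- compute_ranks(out)
    out$run <- trials$run[i]; out$trial <- trials$trial[i]
    fix[[i]] <- out
    beh[[i]] <- b
  }
  trials <- cbind(trials, do.call(rbind, beh))
  list(trials = trials, fixations = do.call(rbind, fix))
}

# Independent oracle: per-sample threshold scan for saccade detection,
# written as a literal loop (velocity by 5-sample central difference,
# acceleration of the velocity vector by 3-sample central difference).
oracle_saccade_scan <- function(trace, vthr = 30, athr = 9500, min_len = 4L) {
  n <- nrow(trace)
  dt <- (trace$time_ms[2] - trace$time_ms[1]) / 1000
  vx <- rep(0, n); vy <- rep(0, n)
  for (i in 3:(n - 2)) {
    vx[i] <- (trace$x_deg[i + 2] - trace$x_deg[i - 2]) / (4 * dt)
    vy[i] <- (trace$y_deg[i + 2] - trace$y_deg[i - 2]) / (4 * dt)
  }
  sp <- sqrt(vx^2 + vy^2)
  ax <- rep(0, n); ay <- rep(0, n)
  for (i in 2:(n - 1)) {
    ax[i] <- (vx[i + 1] - vx[i - 1]) / (2 * dt)
    ay[i] <- (vy[i + 1] - vy[i - 1]) / (2 * dt)
  }
  acc <- sqrt(ax^2 + ay^2)
  out <- NULL
  i <- 1
  while (i <= n) {
    if (sp[i] > vthr) {
      j <- i
      while (j < n && sp[j + 1] > vthr) j <- j + 1
      if (j - i + 1 >= min_len && max(acc[i:j]) >= athr) {
        out <- rbind(out, c(trace$time_ms[i], trace$time_ms[j] + dt * 1000))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# A synthetic trace containing hand-placed minimum-jerk saccades between
# fixed positions, used for detector tests.
make_ramp_trace <- function(positions, dwell_ms = 200, sacc_ms = 24,
                            dt_ms = 2, noise_sd = 0) {
  mj <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  xs <- c(); ys <- c()
  for (k in seq_len(nrow(positions))) {
    nd <- dwell_ms / dt_ms
    xs <- c(xs, rep(positions[k, 1], nd)); ys <- c(ys, rep(positions[k, 2], nd))
    if (k < nrow(positions)) {
      m <- sacc_ms / dt_ms
      s <- mj(seq_len(m) / (m + 1))
      xs <- c(xs, positions[k, 1] + (positions[k + 1, 1] - positions[k, 1]) * s)
      ys <- c(ys, positions[k, 2] + (positions[k + 1, 2] - positions[k, 2]) * s)
    }
  }
  if (noise_sd > 0) {
    xs <- xs + rnorm(length(xs), 0, noise_sd)
    ys <- ys + rnorm(length(ys), 0, noise_sd)
  }
  data.frame(time_ms = (seq_along(xs) - 1) * dt_ms, x_deg = xs, y_deg = ys)
}
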