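# BOLD forward model: voxel time courses = baseline + sum over events of
# amplitude x pattern x HRF(t - onset), sampled at TR, plus low-frequency
# cosine drift, AR(1) Gaussian noise, and motion nuisance series.

#' Ground-truth effect regions for the simulation grid
#'
#' Three disjoint box regions embedded in the voxel grid:
#' * an *amplitude* region where targets evoke stronger responses than rare
#'   distractors which evoke stronger responses than common distractors
#'   (default amplitudes 1.0 / 0.5 / 0.2 arbitrary BOLD units, uniform over
#'   voxels) — the analogue of an IPS-like amplitude effect;
#' * a *pattern-only* region where targets and rare distractors have equal
#'   mean amplitude but distinct, run-stable multivoxel patterns (per-voxel
#'   multipliers with mean exactly 1) — the analogue of a TPJ-like
#'   information-without-amplitude effect;
#' * a *null* region with no event-related signal.
#'
#' Pattern vectors are drawn fresh per call (i.e., per subject) and are
#' centered so both class means are exactly equal.
#'
#' @param dim Integer length-3 voxel grid dimensions.
#' @param amplitude_amps Named amplitudes (`T`, `RD`, `CD`) in the amplitude
#'   region.
#' @param pattern_amps Named amplitudes in the pattern-only region (equal `T`
#'   and `RD` means).
#' @param pattern_sd SD of the per-voxel pattern multipliers around 1.
#' @param rng_seed Optional integer seed (pattern draw).
#' @return List of class `fixfmri_regions`; each region has `name`, `voxels`
#'   (linear indices into the grid), `amplitude` (named per class), and
#'   `pattern` (list of per-voxel multiplier vectors per class).
#' @export
ground_truth_regions <- function(dim = c(24, 24, 16),
                                 amplitude_amps = c(T = 1, RD = 0.5, CD = 0.2),
                                 pattern_amps = c(T = 1, RD = 1, CD = 0.2),
                                 pattern_sd = 0.5,
                                 rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  box <- function(fx, fy, fz) {
    rng <- function(f, n) max(1L, round(f[1] * n)):min(n, round(f[2] * n))
    idx <- expand.grid(x = rng(fx, dim[1]), y = rng(fy, dim[2]), z = rng(fz, dim[3]))
    as.integer((idx$z - 1) * dim[1] * dim[2] + (idx$y - 1) * dim[1] + idx$x)
  }
  amp_vox <- box(c(0.15, 0.33), c(0.15, 0.33), c(0.28, 0.50))
  pat_vox <- box(c(0.67, 0.85), c(0.67, 0.85), c(0.55, 0.75))
  nul_vox <- box(c(0.67, 0.85), c(0.15, 0.33), c(0.28, 0.50))
  flat <- function(n) rep(1, n)
  centered <- function(n) 1 + (z <- stats::rnorm(n, 0, pattern_sd)) - mean(z)
  regions <- list(
    list(name = "amplitude", voxels = amp_vox, amplitude = amplitude_amps,
         pattern = list(T = flat(length(amp_vox)), RD = flat(length(amp_vox)),
                        CD = flat(length(amp_vox)))),
    list(name = "pattern", voxels = pat_vox, amplitude = pattern_amps,
         pattern = list(T = centered(length(pat_vox)),
                        RD = centered(length(pat_vox)),
                        CD = flat(length(pat_vox)))),
    list(name = "null", voxels = nul_vox, amplitude = c(T = 0, RD = 0, CD = 0),
         pattern = list(T = flat(length(nul_vox)), RD = flat(length(nul_vox)),
                        CD = flat(length(nul_vox)))))
  structure(list(dim = dim, regions = regions), class = "fixfmri_regions")
}

#' Simulate a run of 4-D BOLD data
#'
#' @param events data.frame of forward-model events: `onset_ms` (run clock,
#'   volume 1 acquired at t = 0) and `class` (`T`, `RD`, `CD`).
#' @param regions A [ground_truth_regions()] object.
#' @param run_duration_ms Run length; volumes cover it at `tr_ms` spacing.
#' @param tr_ms Repetition time (default 1250 ms).
#' @param baseline Baseline BOLD value.
#' @param noise_sd Stationary SD of the AR(1) voxel noise (0 for none).
#' @param ar1_rho AR(1) coefficient in `[0, 1)`.
#' @param drift_sd SD of the random low-frequency drift (0 for none). Drift is
#'   a random combination of cosine basis functions whose periods exceed
#'   192 s, strictly inside the span of the 1/128 Hz high-pass basis, so the
#'   GLM removes it by construction.
#' @param motion_step_mm,motion_step_rad Random-walk step SDs for the six
#'   simulated motion series.
#' @param n_discarded_leading Leading volumes the analysis will discard.
#' @param rng_seed Optional integer seed.
#' @return List of class `fixfmri_bold`: `data` (matrix voxels x volumes, in
#'   array linear-index order), `dim`, `tr_ms`, `n_vols`, `mask` (logical
#'   vector), `n_discarded_leading`, `motion` (matrix volumes x 6), `voxel_size_mm`.
#' @export
simulate_bold <- function(events, regions, run_duration_ms,
                          tr_ms = 1250, baseline = 100,
                          noise_sd = 1, ar1_rho = 0.3, drift_sd = 2,
                          motion_step_mm = 0.01, motion_step_rad = 2e-4,
                          n_discarded_leading = 2L, rng_seed = NULL) {
  stopifnot(ar1_rho >= 0, ar1_rho < 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  dim3 <- regions$dim
  nvox <- prod(dim3)
  n_vols <- as.integer(ceiling(run_duration_ms / tr_ms))
  times_s <- (seq_len(n_vols) - 1) * tr_ms / 1000
  if (nrow(events) > 0 && any(events$onset_ms / 1000 > times_s[n_vols])) {
    stop("event onset falls after the last volume", call. = FALSE)
  }

  Y <- matrix(baseline, nrow = nvox, ncol = n_vols)
  classes <- c("T", "RD", "CD")
  regs <- lapply(classes, function(cl) {
    hrf_regressor(events$onset_ms[events$class == cl] / 1000, times_s)
  })
  names(regs) <- classes
  for (reg in regions$regions) {
    for (cl in classes) {
      a <- reg$amplitude[[cl]]
      if (a == 0 || all(regs[[cl]] == 0)) next
      Y[reg$voxels, ] <- Y[reg$voxels, ] +
        (a * reg$pattern[[cl]]) %o% regs[[cl]]
    }
  }

  if (drift_sd > 0) {
    # cosine basis over the retained volumes, evaluated on all volumes so that
    # restricted to the retained ones it coincides exactly with the GLM's
    # high-pass basis
    n_ret <- n_vols - n_discarded_leading
    k_max <- max(1L, floor(2 * n_ret * (tr_ms / 1000) / 192))
    i <- seq_len(n_vols) - 1 - n_discarded_leading
    basis <- sapply(seq_len(k_max), function(k) {
      cos(pi * k * (2 * i + 1) / (2 * n_ret))
    })
    coef <- matrix(stats::rnorm(nvox * k_max, 0, drift_sd / sqrt(k_max)),
                   nrow = nvox)
    Y <- Y + coef %*% t(basis)
  }

  if (noise_sd > 0) {
    innov <- matrix(stats::rnorm(n_vols * nvox, 0,
                                 noise_sd * sqrt(1 - ar1_rho^2)),
                    nrow = n_vols)
    innov[1, ] <- stats::rnorm(nvox, 0, noise_sd)
    E <- if (ar1_rho > 0) {
      stats::filter(innov, ar1_rho, method = "recursive")
    } else innov
    Y <- Y + t(E)
  }

  motion <- sapply(seq_len(6), function(j) {
    step <- if (j <= 3) motion_step_mm else motion_step_rad
    cumsum(stats::rnorm(n_vols, 0, step))
  })

  structure(list(data = Y, dim = dim3, tr_ms = tr_ms, n_vols = n_vols,
                 mask = rep(TRUE, nvox), n_discarded_leading = n_discarded_leading,
                 motion = motion, voxel_size_mm = 2.5),
            class = "fixfmri_bold")
}
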