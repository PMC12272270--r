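# First-level fixation-event GLM: 8 task regressors (duration-0 impulses
# convolved with the canonical HRF), cosine high-pass drift basis (1/128 Hz),
# 6 motion nuisance columns, intercept; AR(1) prewhitening; contrasts;
# second-level one-sample t; ROI percent signal change.

# The 8 task regressors: event class crossed with source condition.
TASK_COLUMNS <- c("T.1T_0RD", "T.1T_1RD", "RD.0T_1RD", "RD.1T_1RD",
                  "CD_T.1T_0RD", "CD_T.1T_1RD", "CD_RD.0T_1RD", "CD_RD.1T_1RD")

#' First-level GLM configuration
#'
#' @param tr_ms Repetition time, ms.
#' @param highpass_cutoff_s High-pass cutoff period (drift basis periods are
#'   at least this long), seconds.
#' @param ar1 Model residual autocorrelation with AR(1) prewhitening.
#' @param smoothing_fwhm_mm Spatial smoothing applied to the data for the
#'   standard (amplitude) analysis; the pattern analysis uses unsmoothed data.
#' @param n_discarded_leading Leading volumes discarded from each run.
#' @return List of class `fixfmri_glm_config`.
#' @export
glm_config <- function(tr_ms = 1250, highpass_cutoff_s = 128, ar1 = TRUE,
                       smoothing_fwhm_mm = 6, n_discarded_leading = 2L) {
  stopifnot(highpass_cutoff_s > 2 * tr_ms / 1000, smoothing_fwhm_mm >= 0)
  structure(list(tr_ms = tr_ms, highpass_cutoff_s = highpass_cutoff_s,
                 ar1 = ar1, smoothing_fwhm_mm = smoothing_fwhm_mm,
                 n_discarded_leading = as.integer(n_discarded_leading),
                 event_duration_s = 0, global_normalization = "none"),
            class = "fixfmri_glm_config")
}

# Number of cosine drift functions for n_scans volumes at tr_s with the given
# cutoff period: k-th function has period 2 * n * tr / k, so k <= 2 n tr / cutoff.
n_drift_functions <- function(n_scans, tr_s, cutoff_s) {
  max(0L, floor(2 * n_scans * tr_s / cutoff_s))
}

# DCT-II style basis (unit amplitude), columns k = 1..K.
drift_basis <- function(n_scans, K) {
  if (K == 0) return(matrix(numeric(0), nrow = n_scans, ncol = 0))
  i <- seq_len(n_scans) - 1
  sapply(seq_len(K), function(k) cos(pi * k * (2 * i + 1) / (2 * n_scans)))
}

#' Build the first-level design matrix for one run
#'
#' Task columns are duration-0 event impulses convolved with the canonical
#' HRF, sampled at the acquisition times of the retained volumes (the first
#' `n_discarded_leading` volumes are dropped; onsets stay on the original run
#' clock). Unmatched events, catch trials, error trials and the all-common
#' condition are simply absent from the matched event table and therefore
#' remain in the implicit baseline. Adds the cosine drift basis, six motion
#' columns, and an intercept.
#'
#' @param events Matched events for this run ([matched_event_table()] rows):
#'   `class` (`T`, `RD`, `CD_T`, `CD_RD`), `condition`, `onset_ms` (run clock).
#' @param n_vols Total number of volumes acquired in the run.
#' @param motion Matrix (volumes x 6) of motion parameters, or `NULL`.
#' @param config [glm_config()].
#' @return List of class `fixfmri_design`: `X` (retained volumes x columns),
#'   `task_cols`, `empty_cols` (task columns with no events, kept and
#'   flagged), `n_drift`, `times_s`.
#' @export
build_design_matrix <- function(events, n_vols, motion = NULL,
                                config = glm_config()) {
  tr_s <- config$tr_ms / 1000
  keep <- seq.int(config$n_discarded_leading + 1L, n_vols)
  times_s <- (keep - 1) * tr_s
  if (nrow(events) > 0 && any(events$onset_ms / 1000 > max(times_s))) {
    stop("event onset after the last retained volume", call. = FALSE)
  }
  lab <- paste(events$class, events$condition, sep = ".")
  task <- sapply(TASK_COLUMNS, function(cl) {
    hrf_regressor(events$onset_ms[lab == cl] / 1000, times_s)
  })
  empty <- TASK_COLUMNS[colSums(abs(task)) == 0]
  n <- length(keep)
  K <- n_drift_functions(n, tr_s, config$highpass_cutoff_s)
  drift <- drift_basis(n, K)
  if (K > 0) colnames(drift) <- paste0("drift", seq_len(K))
  if (is.null(motion)) {
    mot <- matrix(0, nrow = n, ncol = 0)
  } else {
    mot <- motion[keep, , drop = FALSE]
    colnames(mot) <- paste0("motion", seq_len(ncol(mot)))
  }
  X <- cbind(task, mot, drift, intercept = 1)
  structure(list(X = X, task_cols = TASK_COLUMNS, empty_cols = empty,
                 n_drift = K, times_s = times_s,
                 n_discarded_leading = config$n_discarded_leading),
            class = "fixfmri_design")
}

#' Fit the first-level GLM for one run
#'
#' Discards the leading volumes, optionally prewhitens with an AR(1) model
#' whose coefficient is pooled over all mask voxels (estimated from OLS
#' residuals, or supplied), and solves ordinary least squares per voxel.
#' With `rho = 0` the fit is identical to plain OLS. Task columns without
#' events are excluded from estimation and reported with `NA` coefficients.
#'
#' @param bold A `fixfmri_bold` (or list with `data` voxels x volumes matrix,
#'   `dim`, `mask`, `n_vols`).
#' @param design A `fixfmri_design` for the same run.
#' @param config [glm_config()].
#' @param rho `NULL` to estimate the AR(1) coefficient (if `config$ar1`),
#'   or a fixed numeric value.
#' @return List of class `fixfmri_fit`: `beta` (columns x voxels), `sigma2`,
#'   `rho`, `df`, `XtXinv` (whitened), `colnames`, `dim`, `mask`,
#'   `empty_cols`.
#' @export
fit_first_level <- function(bold, design, config = glm_config(), rho = NULL) {
  keep <- seq.int(design$n_discarded_leading + 1L, bold$n_vols)
  Y <- t(bold$data[, keep, drop = FALSE])      # volumes x voxels
  X <- design$X
  if (nrow(X) != nrow(Y)) stop("design rows do not match retained volumes")
  drop_cols <- which(colnames(X) %in% design$empty_cols)
  Xe <- if (length(drop_cols)) X[, -drop_cols, drop = FALSE] else X
  qrX <- qr(Xe)
  if (qrX$rank < ncol(Xe)) {
    bad <- colnames(Xe)[qrX$pivot[(qrX$rank + 1):ncol(Xe)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(rho)) {
    if (config$ar1) {
      B0 <- qr.coef(qrX, Y)
      R <- Y - Xe %*% B0
      num <- sum(R[-1, ] * R[-nrow(R), ])
      den <- sum(R^2)
      rho <- if (den > 0) num / den else 0
      rho <- max(min(rho, 0.99), 0)
    } else {
      rho <- 0
    }
  }
  if (rho != 0) {
    W <- function(M) {
      out <- M
      out[1, ] <- sqrt(1 - rho^2) * M[1, ]
      out[-1, ] <- M[-1, , drop = FALSE] - rho * M[-nrow(M), , drop = FALSE]
      out
    }
    Yw <- W(Y); Xw <- W(Xe)
  } else {
    Yw <- Y; Xw <- Xe
  }
  XtXinv <- solve(crossprod(Xw))
  B <- XtXinv %*% crossprod(Xw, Yw)
  Rw <- Yw - Xw %*% B
  df <- nrow(Xw) - ncol(Xw)
  sigma2 <- colSums(Rw^2) / df
  # reinsert NA rows for empty task columns
  beta <- matrix(NA_real_, nrow = ncol(X), ncol = ncol(Y),
                 dimnames = list(colnames(X), NULL))
  beta[colnames(Xe), ] <- B
  structure(list(beta = beta, sigma2 = sigma2, rho = rho, df = df,
                 XtXinv = XtXinv, est_cols = colnames(Xe),
                 colnames = colnames(X), dim = bold$dim, mask = bold$mask,
                 empty_cols = design$empty_cols),
            class = "fixfmri_fit")
}

#' Contrast vector over the eight task regressors
#'
#' Named contrasts average the two condition-specific regressors of each event
#' class: `"T-CD_T"`, `"RD-CD_RD"`, `"T-RD"`, `"CD_T-CD_RD"` and their
#' reverses.
#'
#' @param name Contrast name, e.g. `"T-RD"`.
#' @return Named numeric vector of length 8 over [TASK_COLUMNS].
#' @export
contrast_vector <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("contrast name must be '<classA>-<classB>'")
  w <- stats::setNames(numeric(length(TASK_COLUMNS)), TASK_COLUMNS)
  for (s in list(c(parts[1], 1), c(parts[2], -1))) {
    cols <- TASK_COLUMNS[sub("\\..*$", "", TASK_COLUMNS) == s[1]]
    if (length(cols) == 0) stop("unknown event class: ", s[1])
    w[cols] <- as.numeric(s[2]) / length(cols)
  }
  w
}

#' Subject-level contrast across runs
#'
#' The contrast estimate is averaged across runs; the t statistic uses the
#' per-run whitened GLS variance `c' (X'X)^{-1} c sigma^2`, combined across
#' runs.
#'
#' @param fits List of `fixfmri_fit`, one per run.
#' @param contrast Contrast name (see [contrast_vector()]) or numeric vector
#'   of length 8 over the task columns.
#' @return List of class `fixfmri_statmap`: `effect` and `t` (3-D arrays),
#'   `df`, `kind`.
#' @export
compute_contrast <- function(fits, contrast) {
  if (is.character(contrast)) contrast <- contrast_vector(contrast)
  if (length(contrast) != length(TASK_COLUMNS)) {
    stop("contrast length must equal the number of task columns (",
         length(TASK_COLUMNS), ")", call. = FALSE)
  }
  dims <- fits[[1]]$dim
  nvox <- prod(dims)
  eff_sum <- numeric(nvox); var_sum <- numeric(nvox); df_sum <- 0
  R <- 0L
  for (fit in fits) {
    cfull <- stats::setNames(numeric(length(fit$colnames)), fit$colnames)
    cfull[TASK_COLUMNS] <- contrast
    if (any(cfull[setdiff(names(cfull), fit$est_cols)] != 0)) {
      # run lacks events for a regressor the contrast needs: skip it
      warning("run skipped: contrast touches an empty (flagged) regressor")
      next
    }
    used <- cfull[fit$est_cols]
    eff_sum <- eff_sum + drop(used %*% fit$beta[fit$est_cols, , drop = FALSE])
    cvc <- drop(t(used) %*% fit$XtXinv %*% used)
    var_sum <- var_sum + cvc * fit$sigma2
    df_sum <- df_sum + fit$df
    R <- R + 1L
  }
  if (R == 0L) stop("no run provides all regressors for this contrast", call. = FALSE)
  effect <- eff_sum / R
  se <- sqrt(var_sum) / R
  t <- ifelse(se > 0, effect / se, 0)
  structure(list(effect = array(effect, dims), t = array(t, dims),
                 df = df_sum, kind = "contrast"),
            class = "fixfmri_statmap")
}

#' Voxelwise one-sample t-test across subjects
#'
#' @param maps List of 3-D arrays (one per subject) or a subjects x voxels
#'   matrix.
#' @param mu Null value (0 for contrasts, 0.5 for accuracy maps).
#' @return List of class `fixfmri_statmap` with `t` (3-D array if input was
#'   arrays), `df = n - 1`, `mean`. Zero-variance voxels get `NA` t.
#' @export
second_level_ttest <- function(maps, mu = 0) {
  dims <- NULL
  if (is.list(maps)) {
    dims <- dim(maps[[1]])
    M <- do.call(rbind, lapply(maps, as.vector))
  } else {
    M <- maps
  }
  if (nrow(M) < 3) stop("need at least 3 subjects")
  n <- nrow(M)
  m <- colMeans(M)
  s <- sqrt(colSums(sweep(M, 2, m)^2) / (n - 1))
  t <- ifelse(s > 0, (m - mu) / (s / sqrt(n)), NA_real_)
  t[is.na(m)] <- NA_real_
  shape <- function(v) if (is.null(dims)) v else array(v, dims)
  structure(list(t = shape(t), mean = shape(m), df = n - 1, kind = "t"),
            class = "fixfmri_statmap")
}

#' Percent signal change per task regressor in a region of interest
#'
#' PSC = 100 x (ROI-mean beta x peak of the unit-event regressor) /
#' (ROI-mean intercept), averaged across runs. Because the canonical HRF is
#' peak-normalized, the unit-event regressor peak is 1.
#'
#' @param fits List of `fixfmri_fit` per run.
#' @param roi_voxels Linear voxel indices of the ROI.
#' @param classes Task columns (default all eight) or event classes.
#' @return Named numeric vector of PSC values (percent).
#' @export
percent_signal_change <- function(fits, roi_voxels, classes = TASK_COLUMNS) {
  cols <- if (all(classes %in% TASK_COLUMNS)) classes else {
    TASK_COLUMNS[sub("\\..*$", "", TASK_COLUMNS) %in% classes]
  }
  vals <- sapply(cols, function(cl) {
    mean(sapply(fits, function(fit) {
      b <- mean(fit$beta[cl, roi_voxels])
      base <- mean(fit$beta["intercept", roi_voxels])
      if (!is.finite(base) || base == 0) stop("zero baseline in ROI")
      100 * b / base
    }))
  })
  stats::setNames(vals, cols)
}

#' Percent signal change per event class (conditions pooled)
#'
#' Averages the two condition-specific regressors of each class, weighting
#' equally, as displayed in condition-wise PSC bar plots.
#'
#' @inheritParams percent_signal_change
#' @return Named numeric vector over `T`, `RD`, `CD_T`, `CD_RD`.
#' @export
psc_by_class <- function(fits, roi_voxels) {
  psc <- percent_signal_change(fits, roi_voxels)
  cls <- sub("\\..*$", "", names(psc))
  out <- tapply(psc, cls, mean)
  out[c("T", "RD", "CD_T", "CD_RD")]
}
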