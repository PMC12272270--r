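# HRF, design construction, AR(1)/GLS estimation, contrasts, smoothing,
# second-level t, cluster inference and percent signal change.

test_that("canonical HRF has the expected shape", {
  h <- canonical_hrf(0.1)
  # numerical argmax oracle on a dense grid of the analytic form
  tt <- seq(0, 32, by = 1e-4)
  dense <- dgamma(tt, 6, 1) - dgamma(tt, 16, 1) / 6
  t_peak_oracle <- tt[which.max(dense)]
  expect_equal((which.max(h) - 1) * 0.1, t_peak_oracle, tolerance = 0.03)
  expect_lt(abs(t_peak_oracle - 5), 0.1)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1, tolerance = 1e-5)
  # exactly one sign change (positive lobe then undershoot)
  s <- sign(h[h != 0])
  expect_equal(sum(diff(s) != 0), 1L)
})

test_that("drift column count equals an independent cosine-basis enumeration", {
  cfg <- glm_config()
  for (n_vols in c(100, 412, 600)) {
    ev <- data.frame(class = "T", condition = "1T_0RD", onset_ms = 10000)
    d <- build_design_matrix(ev, n_vols, motion = NULL, config = cfg)
    n <- n_vols - 2
    # enumeration oracle: count k >= 1 with period 2 n TR / k >= 128 s
    k <- 0
    while (2 * n * 1.25 / (k + 1) >= 128) k <- k + 1
    expect_equal(d$n_drift, k)
    expect_equal(ncol(d$X), 8 + 0 + k + 1)
  }
  # with motion: 8 task + 6 motion + K drift + intercept
  ev <- data.frame(class = "T", condition = "1T_0RD", onset_ms = 10000)
  d <- build_design_matrix(ev, 412, motion = matrix(0.001 * rnorm(412 * 6), 412),
                           config = cfg)
  expect_equal(ncol(d$X), 8 + 6 + d$n_drift + 1)
  expect_equal(nrow(d$X), 410)
})

test_that("a single event regressor peaks about 5 s after onset", {
  ev <- data.frame(class = "T", condition = "1T_0RD", onset_ms = 20000)
  d <- build_design_matrix(ev, 120, config = glm_config())
  reg <- d$X[, "T.1T_0RD"]
  t_peak <- d$times_s[which.max(reg)] - 20
  expect_lt(abs(t_peak - 5), 1.25)  # within one TR of the HRF peak
})

test_that("noiseless data generated from the design are recovered exactly", {
  set.seed(8)
  ev <- data.frame(class = c("T", "RD", "CD_T", "CD_RD"),
                   condition = c("1T_0RD", "0T_1RD", "1T_0RD", "0T_1RD"),
                   onset_ms = c(10000, 40000, 80000, 120000))
  n_vols <- 150L
  mot <- matrix(rnorm(n_vols * 6, 0, 0.01), n_vols)
  d <- build_design_matrix(ev, n_vols, mot, glm_config())
  est <- setdiff(colnames(d$X), d$empty_cols)
  true_beta <- setNames(rep(0, length(est)), est)
  true_beta[c("T.1T_0RD", "RD.0T_1RD", "intercept")] <- c(2, -1, 50)
  Y <- d$X[, est] %*% true_beta
  bold <- list(data = t(Y)[rep(1, 5), , drop = FALSE] * 0 + matrix(rep(t(Y), each = 5), 5),
               dim = c(5, 1, 1), mask = rep(TRUE, 5), n_vols = n_vols)
  # prepend the two discarded volumes
  bold$data <- cbind(matrix(50, 5, 2), bold$data)
  fit <- fit_first_level(bold, d, glm_config())
  expect_equal(unname(fit$beta["T.1T_0RD", ]), rep(2, 5), tolerance = 1e-8)
  expect_equal(unname(fit$beta["RD.0T_1RD", ]), rep(-1, 5), tolerance = 1e-8)
  expect_equal(unname(fit$beta["CD_T.1T_0RD", ]), rep(0, 5), tolerance = 1e-8)
  expect_true(all(is.na(fit$beta[d$empty_cols, ])))
})

test_that("AR(1) off equals AR(1) on when the data are white", {
  set.seed(12)
  rg <- ground_truth_regions(c(5, 5, 3))
  ev <- data.frame(onset_ms = c(20000, 70000), class = c("T", "RD"))
  b <- simulate_bold(ev, rg, 150 * 1250, noise_sd = 1, ar1_rho = 0,
                     drift_sd = 0, rng_seed = 3)
  evg <- data.frame(class = c("T", "RD"), condition = c("1T_0RD", "0T_1RD"),
                    onset_ms = ev$onset_ms)
  d <- build_design_matrix(evg, b$n_vols, b$motion)
  f1 <- fit_first_level(b, d, glm_config(ar1 = FALSE))
  f2 <- fit_first_level(b, d, glm_config(ar1 = TRUE))
  expect_lt(abs(f2$rho), 0.08)
  expect_equal(f1$beta["T.1T_0RD", ], f2$beta["T.1T_0RD", ], tolerance = 0.02)
})

test_that("prewhitened fit matches an explicit GLS oracle at fixed rho", {
  set.seed(13)
  n <- 100; nv <- 20; rho <- 0.4
  ev <- data.frame(class = c("T", "RD"), condition = c("1T_0RD", "0T_1RD"),
                   onset_ms = c(15000, 60000))
  d <- build_design_matrix(ev, n + 2L, config = glm_config())
  est <- setdiff(colnames(d$X), d$empty_cols)
  X <- d$X[, est]
  Y <- matrix(rnorm(n * nv), n, nv) + outer(X[, "T.1T_0RD"], rnorm(nv, 2))
  bold <- list(data = cbind(matrix(0, nv, 2), t(Y)), dim = c(nv, 1, 1),
               mask = rep(TRUE, nv), n_vols = n + 2L)
  fit <- fit_first_level(bold, d, glm_config(), rho = rho)
  # GLS oracle by explicit AR(1) covariance inversion
  Sig <- rho^abs(outer(1:n, 1:n, "-")) / (1 - rho^2)
  Sinv <- solve(Sig)
  B_or <- solve(t(X) %*% Sinv %*% X, t(X) %*% Sinv %*% Y)
  expect_equal(unname(fit$beta[est, ]), unname(B_or), tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the collinear columns", {
  ev <- data.frame(class = "T", condition = "1T_0RD", onset_ms = 10000)
  d <- build_design_matrix(ev, 100, config = glm_config())
  d$X <- cbind(d$X, dup = d$X[, "intercept"])
  bold <- list(data = matrix(rnorm(300), 3, 100), dim = c(3, 1, 1),
               mask = rep(TRUE, 3), n_vols = 100L)
  expect_error(fit_first_level(bold, d), "collinear")
})

test_that("contrasts behave linearly and match the hand t formula on a toy fit", {
  set.seed(14)
  ev <- data.frame(class = c("T", "RD"), condition = c("1T_0RD", "0T_1RD"),
                   onset_ms = c(15000, 70000))
  d <- build_design_matrix(ev, 122, config = glm_config())
  est <- setdiff(colnames(d$X), d$empty_cols)
  X <- d$X[, est]
  y <- drop(X %*% c(3, 1, rnorm(ncol(X) - 3, 0, 0.1), 20)) + rnorm(120, 0, 0.5)
  bold <- list(data = matrix(c(0, 0, y), 1), dim = c(1, 1, 1), mask = TRUE,
               n_vols = 122L)
  fit <- fit_first_level(bold, d, glm_config(ar1 = FALSE))
  # only the populated regressors get weight (the toy run has no 1T_1RD events)
  cw <- setNames(numeric(8), c("T.1T_0RD", "T.1T_1RD", "RD.0T_1RD", "RD.1T_1RD",
                               "CD_T.1T_0RD", "CD_T.1T_1RD", "CD_RD.0T_1RD",
                               "CD_RD.1T_1RD"))
  cw["T.1T_0RD"] <- 1; cw["RD.0T_1RD"] <- -1
  sm <- compute_contrast(list(fit), cw)
  # hand formula: t = c'b / sqrt(c' (X'X)^-1 c s2)
  cfull <- setNames(numeric(length(est)), est)
  cfull["T.1T_0RD"] <- 1
  cfull["RD.0T_1RD"] <- -1
  cfull <- cfull[est]
  b <- qr.coef(qr(X), y)
  res <- y - X %*% b
  s2 <- sum(res^2) / (120 - ncol(X))
  t_hand <- sum(cfull * b) / sqrt(drop(t(cfull) %*% solve(crossprod(X)) %*% cfull) * s2)
  expect_equal(as.vector(sm$t), t_hand, tolerance = 1e-8)
  # zero contrast -> zero map; negation flips sign
  z <- compute_contrast(list(fit), rep(0, 8))
  expect_equal(as.vector(z$effect), 0)
  neg <- compute_contrast(list(fit), -cw)
  expect_equal(as.vector(neg$effect), -as.vector(sm$effect))
  expect_error(compute_contrast(list(fit), c(1, -1)), "length")
})

test_that("gaussian smoothing has the right impulse width and preserves structure", {
  dim3 <- c(21, 21, 15)
  img <- array(0, dim3); img[11, 11, 8] <- 1
  sm <- smooth_gaussian(img, fwhm_mm = 6, voxel_size_mm = 2.5)
  # FWHM of the impulse response along x, in voxels (linear interpolation)
  prof <- sm[, 11, 8] / max(sm)
  above <- which(prof >= 0.5)
  lo <- min(above); hi <- max(above)
  interp <- function(i1, i2) {
    i1 + (0.5 - prof[i1]) / (prof[i2] - prof[i1]) * (i2 - i1)
  }
  fwhm_vox <- interp(hi, hi + 1) - interp(lo, lo - 1)
  expect_equal(fwhm_vox, 6 / 2.5, tolerance = 0.1)
  # interior mass preserved
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  # constant image unchanged; fwhm 0 is identity
  cst <- array(3.7, dim3)
  expect_equal(smooth_gaussian(cst, 6, 2.5), cst, tolerance = 1e-12)
  expect_identical(smooth_gaussian(img, 0, 2.5), img)
})

test_that("second-level t matches the hand formula and guards degenerate input", {
  vals <- c(0.3, 0.5, 0.1, 0.4, 0.2)
  maps <- lapply(vals, function(v) array(v, c(2, 2, 2)))
  out <- second_level_ttest(maps, mu = 0)
  t_hand <- mean(vals) / (sd(vals) / sqrt(5))
  expect_equal(out$t[1, 1, 1], t_hand)
  expect_equal(out$df, 4)
  # all-zero maps -> t = NA at zero variance... identical values are flagged
  zmaps <- lapply(1:4, function(i) array(0, c(2, 2, 2)))
  zt <- second_level_ttest(zmaps)
  expect_true(all(is.na(zt$t)))
  expect_error(second_level_ttest(maps[1:2]), "3 subjects")
})

test_that("cluster inference finds a planted blob and nothing in pure noise", {
  set.seed(15)
  dim3 <- c(14, 14, 10)
  blob <- array(0, dim3); blob[5:8, 5:8, 4:6] <- 2
  maps <- lapply(1:10, function(i) blob + array(rnorm(prod(dim3), 0, 0.5), dim3))
  res <- cluster_inference(maps, n_perm = 199, rng_seed = 1)
  sig <- res$table[res$table$significant, ]
  expect_equal(nrow(sig), 1L)
  blob_idx <- which(as.vector(blob) > 0)
  expect_true(all(blob_idx %in% which(as.vector(res$labels) == sig$cluster)))
  # below-threshold map -> empty table
  flat <- lapply(1:10, function(i) array(rnorm(prod(dim3), 0, 1), dim3))
  res0 <- cluster_inference(flat, n_perm = 199, rng_seed = 2)
  expect_true(nrow(res0$table[res0$table$significant, ]) == 0)
  expect_warning(cluster_inference(maps, n_perm = 50, rng_seed = 3), "coarse")
})

test_that("percent signal change is zero for zero betas and scales with amplitude", {
  rg <- ground_truth_regions(c(8, 8, 6))
  ev <- data.frame(onset_ms = c(15000, 60000), class = c("T", "RD"))
  evg <- data.frame(class = c("T", "RD"), condition = c("1T_0RD", "0T_1RD"),
                    onset_ms = ev$onset_ms)
  mk <- function(amps) {
    rg2 <- rg
    rg2$regions[[1]]$amplitude <- amps
    b <- simulate_bold(ev, rg2, 120 * 1250, noise_sd = 0, drift_sd = 0)
    d <- build_design_matrix(evg, b$n_vols, b$motion)
    fit_first_level(b, d, glm_config(ar1 = FALSE))
  }
  amp_vox <- rg$regions[[1]]$voxels
  f1 <- mk(c(T = 1, RD = 0.5, CD = 0.2))
  f2 <- mk(c(T = 2, RD = 1, CD = 0.4))
  p1 <- percent_signal_change(list(f1), amp_vox, c("T.1T_0RD", "RD.0T_1RD"))
  p2 <- percent_signal_change(list(f2), amp_vox, c("T.1T_0RD", "RD.0T_1RD"))
  expect_equal(unname(p2), unname(2 * p1), tolerance = 1e-6)
  expect_equal(unname(p1[1]), 100 * 1 / 100, tolerance = 1e-6)
  # null region: zero betas -> zero PSC
  p0 <- percent_signal_change(list(f1), rg$regions[[3]]$voxels,
                              c("T.1T_0RD", "RD.0T_1RD"))
  expect_equal(unname(p0), c(0, 0), tolerance = 1e-8)
})

test_that("PSC rank order in the amplitude region follows the ground truth", {
  sub <- small_subject()
  psc <- psc_by_class(sub$fits_smoothed, sub$regions$regions[[1]]$voxels)
  expect_gt(psc[["T"]], psc[["RD"]])
  expect_gt(psc[["RD"]], max(psc[["CD_T"]], psc[["CD_RD"]]))
})
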