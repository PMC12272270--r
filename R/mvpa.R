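# Searchlight multivoxel pattern analysis: per-run beta patterns for targets
# vs rare distractors, spherical neighborhoods (radius 4 voxels), a linear
# margin classifier evaluated by leave-one-run-out cross-validation, and a
# group test of accuracy against chance.
#
# Implementation note: for every sphere only the Gram matrix of its (at most)
# 12 exemplar patterns is needed, both for the kernel-ridge margin classifier
# and for the nearest-centroid classifier. Gram entries are sphere-sums of
# voxelwise products of pattern maps, computed for all sphere centers at once
# by zero-padded FFT convolution with the sphere indicator.

#' MVPA configuration
#'
#' @param radius_voxels Searchlight sphere radius in voxels (default 4;
#'   a full interior sphere contains 257 voxels).
#' @param classifier `"linear"` (kernel-ridge linear margin classifier on
#'   demeaned features, fixed regularization `lambda`) or `"centroid"`
#'   (nearest centroid on demeaned features).
#' @param lambda Ridge regularization of the linear classifier.
#' @param min_sphere_voxels Centers whose sphere covers fewer mask voxels are
#'   left undefined (`NA`).
#' @param chance Chance accuracy level (two balanced classes: 0.5).
#' @param accuracy_smoothing_fwhm_mm Smoothing applied to accuracy maps before
#'   the group test.
#' @return List of class `fixfmri_mvpa_config`.
#' @export
mvpa_config <- function(radius_voxels = 4, classifier = c("linear", "centroid"),
                        lambda = 1, min_sphere_voxels = 30, chance = 0.5,
                        accuracy_smoothing_fwhm_mm = 6) {
  classifier <- match.arg(classifier)
  stopifnot(radius_voxels >= 0)
  structure(list(radius_voxels = radius_voxels, classifier = classifier,
                 lambda = lambda, min_sphere_voxels = min_sphere_voxels,
                 chance = chance,
                 accuracy_smoothing_fwhm_mm = accuracy_smoothing_fwhm_mm),
            class = "fixfmri_mvpa_config")
}

#' Lattice offsets of a searchlight sphere
#'
#' All integer offsets with squared Euclidean norm at most `radius^2`.
#' Radius 4 yields 257 offsets.
#'
#' @param radius_voxels Sphere radius in voxels.
#' @return Integer matrix (offsets x 3).
#' @export
sphere_offsets <- function(radius_voxels) {
  r <- floor(radius_voxels)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g[rowSums(g^2) <= radius_voxels^2, , drop = FALSE]
}

#' Voxel indices of a sphere around a center, intersected with the mask
#'
#' @param mask Logical vector over the grid (or `NULL` for all voxels).
#' @param dim3 Grid dimensions.
#' @param center Length-3 voxel coordinate (1-based).
#' @param radius_voxels Sphere radius.
#' @return Integer vector of linear voxel indices.
#' @export
sphere_indices <- function(mask, dim3, center, radius_voxels) {
  off <- sphere_offsets(radius_voxels)
  pts <- sweep(off, 2, as.numeric(center), "+")
  ok <- pts[, 1] >= 1 & pts[, 1] <= dim3[1] &
    pts[, 2] >= 1 & pts[, 2] <= dim3[2] &
    pts[, 3] >= 1 & pts[, 3] <= dim3[3]
  pts <- pts[ok, , drop = FALSE]
  idx <- (pts[, 3] - 1) * dim3[1] * dim3[2] + (pts[, 2] - 1) * dim3[1] + pts[, 1]
  idx <- as.integer(idx)
  if (!is.null(mask)) idx <- idx[mask[idx]]
  idx
}

#' Extract per-run class patterns from first-level fits
#'
#' The two class exemplars per run are the beta maps of targets from the
#' one-target/no-rare condition and rare distractors from the
#' no-target/one-rare condition (the mixed condition and the common
#' distractors are not used for classification).
#'
#' @param fits List of per-run `fixfmri_fit` objects (unsmoothed data).
#' @param classes Character vector of length 2 naming the task columns used as
#'   classes.
#' @return List of class `fixfmri_patterns`: `P` (voxels x exemplars matrix),
#'   `label` (+1 / -1 per exemplar), `run`, `dim`, `mask`, `class_names`.
#' @export
extract_patterns <- function(fits, classes = c("T.1T_0RD", "RD.0T_1RD")) {
  if (length(classes) != 2) stop("exactly 2 classes required")
  if (!all(classes %in% TASK_COLUMNS)) {
    stop("not a classification class: ",
         paste(setdiff(classes, TASK_COLUMNS), collapse = ", "), call. = FALSE)
  }
  cols <- list(); labs <- integer(0); runs <- integer(0)
  for (r in seq_along(fits)) {
    for (j in 1:2) {
      b <- fits[[r]]$beta[classes[j], ]
      if (all(is.na(b))) stop("missing class ", classes[j], " in run ", r)
      cols[[length(cols) + 1]] <- b
      labs <- c(labs, if (j == 1) 1L else -1L)
      runs <- c(runs, r)
    }
  }
  structure(list(P = do.call(cbind, cols), label = labs, run = runs,
                 dim = fits[[1]]$dim, mask = fits[[1]]$mask,
                 class_names = classes),
            class = "fixfmri_patterns")
}

# Sphere-sum of each column of M (voxels x k) over a sphere of given radius,
# by zero-padded FFT convolution. Returns a matrix of the same shape whose
# row v holds the sum of M over the sphere centered at voxel v (truncated at
# the grid boundary).
sphere_sum <- function(M, dim3, radius) {
  r <- floor(radius)
  pd <- dim3 + 2 * r
  kern <- array(0, pd)
  off <- sphere_offsets(radius)
  kidx <- ((off[, 3] %% pd[3])) * pd[1] * pd[2] +
    ((off[, 2] %% pd[2])) * pd[1] + (off[, 1] %% pd[1]) + 1
  kern[kidx] <- 1
  FK <- stats::fft(kern)
  out <- matrix(0, nrow(M), ncol(M))
  pad <- array(0, pd)
  core <- lapply(seq_len(3), function(a) seq_len(dim3[a]))
  for (j in seq_len(ncol(M))) {
    pad[] <- 0
    pad[core[[1]], core[[2]], core[[3]]] <- M[, j]
    cv <- Re(stats::fft(stats::fft(pad) * Conj(FK), inverse = TRUE)) / prod(pd)
    out[, j] <- as.vector(cv[core[[1]], core[[2]], core[[3]]])
  }
  out
}

# Kernel centering on the training exemplars: K~_ab = (x_a - m)'(x_b - m)
# with m the train mean, expressed purely in Gram entries.
center_kernel <- function(K, tr) {
  cm <- colMeans(K[tr, , drop = FALSE])
  tm <- mean(K[tr, tr])
  K - outer(rep(1, nrow(K)), cm) - outer(cm, rep(1, nrow(K))) + tm
}

#' Searchlight leave-one-run-out cross-validation
#'
#' For every voxel of the analysis mask, a sphere of patterns is classified
#' with leave-one-run-out cross-validation: the classifier is trained on the
#' exemplars of all runs but one and tested on the held-out run's two
#' exemplars; the sphere center receives the accuracy averaged over folds.
#' Centers whose sphere covers fewer than `min_sphere_voxels` mask voxels are
#' `NA`.
#'
#' @param patterns A [extract_patterns()] object.
#' @param config [mvpa_config()].
#' @return 3-D accuracy array (values in `[0, 1]`, `NA` where undefined).
#' @export
searchlight_cv <- function(patterns, config = mvpa_config()) {
  P <- patterns$P
  dim3 <- patterns$dim
  mask <- patterns$mask
  n_ex <- ncol(P)
  runs <- patterns$run
  y <- patterns$label
  if (length(unique(runs)) < 2) stop("need at least 2 runs")
  P0 <- P
  P0[!mask | !is.finite(P[, 1]), ] <- 0

  # Gram entries for all centers at once: products of exemplar maps,
  # sphere-summed. 78 unique (i <= j) product maps for 12 exemplars.
  pairs <- which(upper.tri(matrix(0, n_ex, n_ex), diag = TRUE), arr.ind = TRUE)
  prod_maps <- P0[, pairs[, 1], drop = FALSE] * P0[, pairs[, 2], drop = FALSE]
  S <- sphere_sum(prod_maps, dim3, config$radius_voxels)
  counts <- drop(sphere_sum(matrix(as.numeric(mask), ncol = 1), dim3,
                            config$radius_voxels))

  acc <- rep(NA_real_, prod(dim3))
  centers <- which(mask & counts >= config$min_sphere_voxels)
  folds <- lapply(sort(unique(runs)), function(r) {
    list(tr = which(runs != r), te = which(runs == r))
  })
  K <- matrix(0, n_ex, n_ex)
  ut <- upper.tri(K, diag = TRUE)
  for (v in centers) {
    K[ut] <- S[v, ]
    K[lower.tri(K)] <- t(K)[lower.tri(K)]
    correct <- 0L; total <- 0L
    for (f in folds) {
      Kc <- center_kernel(K, f$tr)
      pred <- if (config$classifier == "linear") {
        a <- solve(Kc[f$tr, f$tr] + config$lambda * diag(length(f$tr)),
                   y[f$tr])
        sign(drop(Kc[f$te, f$tr, drop = FALSE] %*% a))
      } else {
        # nearest centroid in (demeaned) feature space via kernel distances
        sapply(f$te, function(te) {
          d <- sapply(c(1L, -1L), function(cls) {
            idx <- f$tr[y[f$tr] == cls]
            Kc[te, te] - 2 * mean(Kc[te, idx]) + mean(Kc[idx, idx])
          })
          c(1L, -1L)[which.min(d)]
        })
      }
      pred[pred == 0] <- 1L
      correct <- correct + sum(pred == y[f$te])
      total <- total + length(f$te)
    }
    acc[v] <- correct / total
  }
  array(acc, dim3)
}

#' Group test of searchlight accuracy against chance
#'
#' Smooths each subject's accuracy map (6 mm by default), then performs a
#' one-sample t-test against chance with cluster-level FWE by sign-flip
#' permutation, as in the amplitude analysis.
#'
#' @param acc_maps List of per-subject 3-D accuracy arrays.
#' @param config [mvpa_config()].
#' @param voxel_size_mm Voxel size for smoothing.
#' @param p_voxel,alpha,n_perm,rng_seed Passed to [cluster_inference()].
#' @return A `fixfmri_clusters` object (t map is for accuracy minus chance),
#'   plus `mean_accuracy` per significant cluster.
#' @export
group_accuracy_test <- function(acc_maps, config = mvpa_config(),
                                voxel_size_mm = 2.5, p_voxel = 0.001,
                                alpha = 0.05, n_perm = 500, rng_seed = NULL) {
  sm <- lapply(acc_maps, function(a) {
    array(smooth_gaussian(a, config$accuracy_smoothing_fwhm_mm, voxel_size_mm),
          dim(a))
  })
  res <- cluster_inference(sm, mu = config$chance, p_voxel = p_voxel,
                           alpha = alpha, n_perm = n_perm, rng_seed = rng_seed)
  if (nrow(res$table) > 0) {
    Msm <- do.call(rbind, lapply(sm, as.vector))
    res$table$mean_accuracy <- vapply(res$table$cluster, function(cl) {
      mean(Msm[, as.vector(res$labels) == cl], na.rm = TRUE)
    }, numeric(1))
  }
  res
}
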