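# Cluster-level inference: one-sided voxel threshold, 26-connectivity
# components, and family-wise error control on cluster size by sign-flip
# permutation of the subject maps.

# 26-connectivity offsets (all neighbors sharing a face, edge or corner).
neighbor_offsets_26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

#' Label 26-connected clusters of suprathreshold voxels
#'
#' @param above Logical 3-D array (or vector with `dim3`).
#' @param dim3 Spatial dimensions if `above` is a vector.
#' @return Integer vector of cluster labels (0 = below threshold), same length
#'   as `above`.
#' @export
label_clusters <- function(above, dim3 = dim(above)) {
  above <- as.vector(above)
  labels <- integer(length(above))
  idx <- which(above)
  if (length(idx) == 0) return(labels)
  coords <- arrayInd(idx, dim3)
  key <- function(m) (m[, 3] - 1) * dim3[1] * dim3[2] + (m[, 2] - 1) * dim3[1] + m[, 1]
  in_set <- logical(length(above)); in_set[idx] <- TRUE
  lab <- 0L
  for (seed in idx) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    queue <- seed
    labels[seed] <- lab
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      c0 <- arrayInd(v, dim3)
      nb <- sweep(neighbor_offsets_26, 2, as.numeric(c0), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dim3[1] &
        nb[, 2] >= 1 & nb[, 2] <= dim3[2] &
        nb[, 3] >= 1 & nb[, 3] <= dim3[3]
      cand <- key(nb[ok, , drop = FALSE])
      cand <- cand[in_set[cand] & labels[cand] == 0L]
      labels[cand] <- lab
      queue <- c(queue, cand)
    }
  }
  labels
}

# One-sided t map across subject maps (rows = subjects), vectorized.
group_t <- function(M, mu = 0) {
  n <- nrow(M)
  m <- colMeans(M)
  s2 <- (colSums(M^2) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  ifelse(s2 > 0, (m - mu) / sqrt(s2 / n), 0)
}

max_cluster_size <- function(t_vec, thr, dim3, valid) {
  above <- t_vec > thr & valid
  if (!any(above)) return(0L)
  labels <- label_clusters(above, dim3)
  max(tabulate(labels))
}

#' Cluster-level FWE inference by sign-flip permutation
#'
#' Thresholds the one-sided group t map at an uncorrected voxel p-value,
#' forms 26-connected clusters, and assigns each a family-wise-error-corrected
#' p-value from the permutation distribution of the maximal cluster size under
#' random sign flips of the (mean-centered) subject maps.
#'
#' @param subject_maps List of 3-D arrays or a subjects x voxels matrix.
#' @param dim3 Spatial dimensions (required for matrix input).
#' @param mu Null value subtracted from each map (0 for contrasts, 0.5 for
#'   accuracy maps).
#' @param p_voxel Uncorrected one-sided voxel threshold (default 0.001).
#' @param alpha Cluster-level FWE threshold (default 0.05).
#' @param n_perm Number of sign-flip permutations (default 500; fewer than
#'   100 triggers a warning).
#' @param rng_seed Optional integer seed for the sign flips.
#' @return List of class `fixfmri_clusters`: `table` (data.frame `cluster`,
#'   `peak_x`, `peak_y`, `peak_z`, `k`, `peak_t`, `p_fwe`, `significant`),
#'   `t_map` (3-D array), `threshold_t`, `df`.
#' @export
cluster_inference <- function(subject_maps, dim3 = NULL, mu = 0,
                              p_voxel = 0.001, alpha = 0.05, n_perm = 500,
                              rng_seed = NULL) {
  if (is.list(subject_maps)) {
    dim3 <- dim(subject_maps[[1]])
    M <- do.call(rbind, lapply(subject_maps, as.vector))
  } else {
    M <- subject_maps
    if (is.null(dim3)) stop("dim3 required for matrix input")
  }
  if (n_perm < 100) warning("fewer than 100 permutations: FWE p-values are coarse")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  M <- M - mu
  valid <- apply(is.finite(M), 2, all)
  M[, !valid] <- 0
  n <- nrow(M)
  df <- n - 1
  thr <- stats::qt(1 - p_voxel, df)
  t_obs <- group_t(M)
  above <- t_obs > thr & valid
  labels <- label_clusters(above, dim3)
  n_clus <- max(labels, 0L)

  null_max <- integer(n_perm)
  for (p in seq_len(n_perm)) {
    signs <- sample(c(-1, 1), n, replace = TRUE)
    null_max[p] <- max_cluster_size(group_t(signs * M), thr, dim3, valid)
  }

  if (n_clus == 0) {
    tab <- data.frame(cluster = integer(0), peak_x = integer(0),
                      peak_y = integer(0), peak_z = integer(0), k = integer(0),
                      peak_t = numeric(0), p_fwe = numeric(0),
                      significant = logical(0))
  } else {
    tab <- do.call(rbind, lapply(seq_len(n_clus), function(cl) {
      vox <- which(labels == cl)
      peak <- vox[which.max(t_obs[vox])]
      co <- arrayInd(peak, dim3)
      k <- length(vox)
      p_fwe <- (1 + sum(null_max >= k)) / (n_perm + 1)
      data.frame(cluster = cl, peak_x = co[1], peak_y = co[2], peak_z = co[3],
                 k = k, peak_t = t_obs[peak], p_fwe = p_fwe,
                 significant = p_fwe < alpha)
    }))
    tab <- tab[order(-tab$k), ]
    rownames(tab) <- NULL
  }
  structure(list(table = tab, t_map = array(t_obs, dim3), threshold_t = thr,
                 df = df, labels = array(labels, dim3)),
            class = "fixfmri_clusters")
}
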