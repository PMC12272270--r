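# Separable 3-D Gaussian smoothing with edge renormalization.

# Banded Gaussian kernel matrix for one axis (truncated at 4 sigma).
gauss_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  i <- seq_len(n)
  K <- exp(-outer(i, i, "-")^2 / (2 * sigma_vox^2))
  K[abs(outer(i, i, "-")) > ceiling(4 * sigma_vox)] <- 0
  K / sum(exp(-(-(ceiling(4 * sigma_vox)):ceiling(4 * sigma_vox))^2 /
                (2 * sigma_vox^2)))
}

# Apply kernel matrices along the three spatial axes of a (possibly 4-D)
# array stored as voxels x frames matrix with spatial dims `dim3`.
apply_separable <- function(M, dim3, Ks) {
  n1 <- dim3[1]; n2 <- dim3[2]; n3 <- dim3[3]
  nf <- ncol(M)
  A <- array(M, c(n1, n2, n3 * nf))
  A <- array(Ks[[1]] %*% matrix(A, n1, n2 * n3 * nf), c(n1, n2, n3, nf))
  A <- aperm(A, c(2, 1, 3, 4))
  A <- array(Ks[[2]] %*% matrix(A, n2, n1 * n3 * nf), c(n2, n1, n3, nf))
  A <- aperm(A, c(3, 2, 1, 4))
  A <- array(Ks[[3]] %*% matrix(A, n3, n1 * n2 * nf), c(n3, n1, n2, nf))
  A <- aperm(A, c(2, 3, 1, 4))
  matrix(A, n1 * n2 * n3, nf)
}

#' Gaussian spatial smoothing
#'
#' Separable Gaussian with `sigma = fwhm / (2 sqrt(2 log 2))` per axis in
#' voxel units. Edge effects are removed by renormalization (the smoothed
#' image is divided by the smoothed all-ones image), so constant images are
#' unchanged and interior impulse responses keep their mass. `fwhm = 0` is the
#' identity. Voxels that are `NA` (or excluded by `valid`) contribute nothing
#' and are renormalized away; they are returned as `NA`.
#'
#' @param x 3-D array, or voxels x frames matrix (with `dim3` given), or a
#'   `fixfmri_bold` (all volumes smoothed).
#' @param fwhm_mm Full width at half maximum, mm.
#' @param voxel_size_mm Voxel edge length, mm.
#' @param dim3 Spatial dimensions when `x` is a matrix.
#' @param valid Optional logical vector of valid voxels.
#' @return Same shape as the input.
#' @export
smooth_gaussian <- function(x, fwhm_mm, voxel_size_mm = 2.5, dim3 = NULL,
                            valid = NULL) {
  stopifnot(fwhm_mm >= 0)
  if (inherits(x, "fixfmri_bold")) {
    out <- x
    out$data <- smooth_gaussian(x$data, fwhm_mm, x$voxel_size_mm, dim3 = x$dim,
                                valid = valid)
    return(out)
  }
  if (is.array(x) && length(dim(x)) == 3) {
    dim3 <- dim(x)
    return(array(smooth_gaussian(matrix(as.vector(x), ncol = 1), fwhm_mm,
                                 voxel_size_mm, dim3, valid), dim3))
  }
  if (fwhm_mm == 0) return(x)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  Ks <- lapply(dim3, gauss_kernel_matrix, sigma_vox = sigma)
  M <- as.matrix(x)
  na_mask <- !is.finite(M[, 1])
  if (is.null(valid)) valid <- !na_mask else valid <- valid & !na_mask
  M[!valid, ] <- 0
  num <- apply_separable(M, dim3, Ks)
  den <- apply_separable(matrix(as.numeric(valid), ncol = 1), dim3, Ks)
  out <- sweep(num, 1, drop(den), "/")
  out[!valid, ] <- NA_real_
  out
}
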