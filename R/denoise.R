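#' Local-PCA denoising of a 4-D diffusion-weighted volume
#'
#' Sliding-window local principal component analysis: for each cubic patch of
#' radius `patch_radius` (edge `2r + 1`), the (voxels x volumes) patch matrix
#' is mean-centred, eigen-decomposed, and its noise components suppressed.
#' When `noise_sigma` is not given, the number of noise components and the
#' noise level are estimated per patch from the tail of the eigenvalue
#' spectrum using the Marchenko-Pastur law for pure-noise covariance
#' eigenvalues; with a known `noise_sigma`, eigenvalues at or below
#' `sigma^2 * (1 + sqrt(N/M))^2` are suppressed. Denoised patches are
#' averaged over all overlapping windows.
#'
#' A noiseless (exactly low-rank) input is a fixed point up to numerical
#' tolerance, and patch means are preserved, so homogeneous-region mean
#' signal is untouched.
#'
#' @param dwi 4-D array (x, y, z, volume).
#' @param patch_radius patch radius in voxels; patch edge is `2r + 1`. A
#'   patch with fewer voxels than volumes still works but estimates the
#'   spectrum less stably.
#' @param noise_sigma known noise standard deviation, or `NULL` (default)
#'   for Marchenko-Pastur auto-estimation.
#' @return denoised 4-D array of the same dimensions.
#' @export
denoise_local_pca <- function(dwi, patch_radius = 2L, noise_sigma = NULL) {
  dm <- dim(dwi)
  if (length(dm) != 4) stop("dwi must be a 4-D array")
  r <- as.integer(patch_radius)
  edge <- 2L * r + 1L
  if (any(dm[1:3] < edge))
    stop("patch (edge ", edge, ") larger than volume (",
         paste(dm[1:3], collapse = "x"), ")")
  nvol <- dm[4]
  grid <- dm[1:3]
  acc_mat <- matrix(0, prod(grid), nvol)
  wt <- numeric(prod(grid))
  dwi_mat <- matrix(dwi, prod(grid), nvol)
  lin_index <- array(seq_len(prod(grid)), grid)

  cx <- seq(1L + r, grid[1] - r)
  cy <- seq(1L + r, grid[2] - r)
  cz <- seq(1L + r, grid[3] - r)
  for (z in cz) for (y in cy) for (x in cx) {
    vox <- as.vector(lin_index[(x - r):(x + r), (y - r):(y + r), (z - r):(z + r)])
    Xd <- denoise_patch(dwi_mat[vox, , drop = FALSE], noise_sigma)
    acc_mat[vox, ] <- acc_mat[vox, ] + Xd
    wt[vox] <- wt[vox] + 1
  }
  # voxels never covered by a full patch keep their input values
  uncovered <- wt == 0
  out_mat <- acc_mat / wt
  out_mat[uncovered, ] <- dwi_mat[uncovered, , drop = FALSE]
  array(out_mat, dm)
}

# denoise one (M voxels x N volumes) patch matrix
denoise_patch <- function(X, noise_sigma = NULL) {
  M <- nrow(X); N <- ncol(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  eg <- eigen(crossprod(Xc) / M, symmetric = TRUE)
  lam <- rev(eg$values)              # ascending
  V <- eg$vectors[, rev(seq_len(N)), drop = FALSE]
  if (is.null(noise_sigma)) {
    keep_from <- mp_signal_start(lam, M)
  } else {
    tau <- noise_sigma^2 * (1 + sqrt(N / M))^2
    keep_from <- match(TRUE, lam > tau)
    if (is.na(keep_from)) keep_from <- N + 1L
  }
  if (keep_from <= 1L) return(X)     # everything is signal
  kill <- seq_len(keep_from - 1L)
  Vn <- V[, kill, drop = FALSE]
  Xd <- Xc - (Xc %*% Vn) %*% t(Vn)
  sweep(Xd, 2, mu, "+")
}

# Marchenko-Pastur tail detection: find the first eigenvalue index (ascending)
# that is inconsistent with a pure-noise bulk. Returns the index of the first
# signal component (N + 1 if all noise).
mp_signal_start <- function(lam_asc, M) {
  N <- length(lam_asc)
  # p = number of signal components; take the smallest p whose remaining
  # lower eigenvalues look like a pure-noise Marchenko-Pastur bulk
  for (p in seq(0L, N - 1L)) {
    noise <- pmax(lam_asc[seq_len(N - p)], 0)
    sig2 <- mean(noise)
    gamma <- (N - p) / M
    spread <- noise[N - p] - noise[1]
    if (spread <= 4 * sig2 * sqrt(gamma) + 1e-300) return(N - p + 1L)
  }
  N + 1L
}

#' Estimate the noise standard deviation of a 4-D volume
#'
#' Median across patch-wise Marchenko-Pastur noise-bulk estimates.
#'
#' @param dwi 4-D array.
#' @param patch_radius patch radius in voxels.
#' @return scalar sigma estimate.
#' @export
estimate_noise_sigma <- function(dwi, patch_radius = 2L) {
  dm <- dim(dwi)
  r <- as.integer(patch_radius)
  nvol <- dm[4]
  grid <- dm[1:3]
  dwi_mat <- matrix(dwi, prod(grid), nvol)
  lin_index <- array(seq_len(prod(grid)), grid)
  cx <- seq(1L + r, grid[1] - r)
  cy <- seq(1L + r, grid[2] - r)
  cz <- seq(1L + r, grid[3] - r)
  ests <- c()
  for (z in cz) for (y in cy) for (x in cx) {
    vox <- as.vector(lin_index[(x - r):(x + r), (y - r):(y + r), (z - r):(z + r)])
    X <- dwi_mat[vox, , drop = FALSE]
    Xc <- sweep(X, 2, colMeans(X))
    lam <- rev(eigen(crossprod(Xc) / nrow(X), symmetric = TRUE,
                     only.values = TRUE)$values)
    st <- mp_signal_start(lam, nrow(X))
    if (st > 1) ests <- c(ests, sqrt(mean(lam[seq_len(st - 1L)])))
  }
  if (length(ests) == 0) 0 else stats::median(ests)
}
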