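#' Specify a labelled tensor-field phantom
#'
#' A phantom is a 3-D grid of labelled tissue compartments, each carrying a
#' ground-truth diffusion tensor D (um^2/ms), kurtosis tensor W and b0 signal
#' S0. An optional lesion specification converts a fraction of white-matter
#' voxels into hyperintensity lesions with override tensors (emulating the
#' reduced kurtosis / raised diffusivity of ischemic lesions), and a CSF
#' label doubles as the ventricle compartment.
#'
#' @param grid integer length-3 grid shape (voxels).
#' @param voxel_mm isotropic voxel size in mm.
#' @param regions list of region definitions, each a list with `label`
#'   (positive integer), `name`, `d6`, `w15`, `S0`, and optional
#'   `compartment` (`"WM"`, `"GM"`, `"CSF"`).
#' @param lesion optional list with `fraction` (of WM voxels turned into
#'   lesions), `d6`, `w15` overrides, and `prob_in`/`prob_out` lesion
#'   probability-map values (defaults 0.9 / 0.05).
#' @param snr b0 signal-to-noise ratio S0/sigma; `Inf` for noiseless.
#' @param seed RNG seed used for voxel assignment and noise.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(10, 10, 10), voxel_mm = 2.5,
                         regions = default_phantom_regions(),
                         lesion = default_lesion_spec(),
                         snr = Inf, seed = 1L) {
  stopifnot(length(grid) == 3, all(grid >= 1), voxel_mm > 0, snr > 0)
  labels <- vapply(regions, function(r) r$label, numeric(1))
  if (anyDuplicated(labels)) stop("region labels must be unique")
  if (any(labels <= 0)) stop("region labels must be positive")
  for (r in regions) {
    ev <- eigen(dt_unpack(r$d6), symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("ground-truth D must be positive definite (", r$name, ")")
  }
  structure(
    list(grid = as.integer(grid), voxel_mm = voxel_mm, regions = regions,
         lesion = lesion, snr = snr, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Default phantom tissue compartments
#'
#' Three compartments with literature-typical adult-brain values: coherent
#' white matter (prolate D, substantial kurtosis), thalamus-like deep gray
#' matter (mildly anisotropic, moderate kurtosis), and CSF (fast isotropic,
#' vanishing kurtosis).
#'
#' @export
default_phantom_regions <- function() {
  dd <- dense_sphere_directions()
  wm <- kt_from_gaussian_mixture(
    list(diag(c(2.2, 0.6, 0.6)), diag(c(1.0, 0.12, 0.12))), c(0.55, 0.45))
  wm$w15 <- scale_w_to_mk(wm$d6, wm$w15, dd, 0.9)
  gm <- kt_from_gaussian_mixture(
    list(diag(c(1.4, 0.9, 0.9)), diag(c(0.7, 0.5, 0.5))), c(0.5, 0.5))
  gm$w15 <- scale_w_to_mk(gm$d6, gm$w15, dd, 0.85)
  list(
    list(label = 1L, name = "white_matter", compartment = "WM",
         d6 = wm$d6, w15 = wm$w15, S0 = 100),
    list(label = 2L, name = "deep_gray", compartment = "GM",
         d6 = gm$d6, w15 = gm$w15, S0 = 110),
    list(label = 3L, name = "csf", compartment = "CSF",
         d6 = dt_pack(diag(3) * 3.0), w15 = rep(0, 15), S0 = 140)
  )
}

#' Default lesion (white-matter hyperintensity) specification
#'
#' Lesioned voxels get raised, less anisotropic diffusivity and reduced
#' kurtosis relative to normal-appearing white matter.
#'
#' @param fraction fraction of WM voxels converted to lesion.
#' @export
default_lesion_spec <- function(fraction = 0.15) {
  les <- kt_from_gaussian_mixture(
    list(diag(c(1.9, 1.1, 1.1)), diag(c(1.3, 0.7, 0.7))), c(0.5, 0.5))
  les$w15 <- scale_w_to_mk(les$d6, les$w15, dense_sphere_directions(), 0.6)
  list(fraction = fraction, d6 = les$d6, w15 = les$w15,
       prob_in = 0.9, prob_out = 0.05)
}

#' Simulate a noisy 4-D diffusion-weighted dataset from a phantom
#'
#' Evaluates the two-shell DKI signal model
#' `S = S0 exp(-b D_app + b^2 D_app^2 K_app / 6)` in every labelled voxel and
#' adds Rician noise as the magnitude of `(S + N(0, sigma)) + i N(0, sigma)`
#' with `sigma = S0 / SNR` per region. The phantom is rejected if its
#' predicted signal increases between shells anywhere (kurtosis term beyond
#' its validity range at `b_max`).
#'
#' @param phantom a `phantom_spec`.
#' @param scheme a `gradient_table`.
#' @return a list with `dwi` (4-D array), `labels` (3-D integer array),
#'   `truth` (named list of ground-truth metric maps), `wmh_prob`
#'   (3-D lesion probability map), `ventricle` (3-D 0/1 mask), `wmh_mask`
#'   (ground-truth lesion voxels), and `sigma_map`.
#' @export
simulate_dwi <- function(phantom, scheme) {
  grid <- phantom$grid
  nvox <- prod(grid)
  nvol <- n_volumes(scheme)
  set.seed(phantom$seed)

  # assign voxels to regions in contiguous blocks along x, proportional shares
  nreg <- length(phantom$regions)
  share <- rep(floor(nvox / nreg), nreg)
  share[nreg] <- nvox - sum(share[-nreg])
  labels_flat <- rep(vapply(phantom$regions, `[[`, integer(1), "label"), share)
  labels <- array(labels_flat, grid)

  # lesion voxels drawn inside WM
  wmh_flat <- rep(FALSE, nvox)
  les <- phantom$lesion
  wm_labels <- vapply(
    phantom$regions,
    function(r) if (identical(r$compartment, "WM")) r$label else NA_integer_,
    integer(1))
  wm_labels <- wm_labels[!is.na(wm_labels)]
  if (!is.null(les) && les$fraction > 0 && length(wm_labels) > 0) {
    wm_idx <- which(labels_flat %in% wm_labels)
    n_les <- round(les$fraction * length(wm_idx))
    if (n_les > 0) wmh_flat[sample(wm_idx, n_les)] <- TRUE
  }

  # per-voxel tensors
  tab <- setNames(phantom$regions,
                  vapply(phantom$regions, function(r) as.character(r$label), ""))
  dwi <- array(0, c(grid, nvol))
  truth <- setNames(lapply(metric_names(), function(nm) array(NA_real_, grid)),
                    metric_names())
  sigma_map <- array(0, grid)
  dwi_mat <- matrix(0, nvox, nvol)

  # validity check + signal evaluation per distinct tissue class
  classes <- unique(data.frame(label = labels_flat, wmh = wmh_flat))
  for (ci in seq_len(nrow(classes))) {
    reg <- tab[[as.character(classes$label[ci])]]
    is_les <- classes$wmh[ci]
    d6 <- if (is_les) les$d6 else reg$d6
    w15 <- if (is_les) les$w15 else reg$w15
    par <- list(S0 = reg$S0, d6 = d6, w15 = w15)
    check_signal_monotone(par, scheme)
    s <- predict_signals(par, scheme)
    m <- compute_metrics(par, scheme)
    vox <- which(labels_flat == classes$label[ci] & wmh_flat == is_les)
    dwi_mat[vox, ] <- matrix(s, length(vox), nvol, byrow = TRUE)
    for (nm in metric_names()) truth[[nm]][vox] <- m[[nm]]
    sigma_map[vox] <- if (is.finite(phantom$snr)) reg$S0 / phantom$snr else 0
  }

  if (is.finite(phantom$snr)) {
    sig <- as.vector(sigma_map)
    noise_re <- matrix(stats::rnorm(nvox * nvol), nvox, nvol) * sig
    noise_im <- matrix(stats::rnorm(nvox * nvol), nvox, nvol) * sig
    dwi_mat <- sqrt((dwi_mat + noise_re)^2 + noise_im^2)
  }
  dwi <- array(dwi_mat, c(grid, nvol))

  prob_in <- if (is.null(les)) 0.9 else les$prob_in
  prob_out <- if (is.null(les)) 0.05 else les$prob_out
  wmh_prob <- array(ifelse(wmh_flat, prob_in, prob_out), grid)
  csf_labels <- vapply(
    phantom$regions,
    function(r) if (identical(r$compartment, "CSF")) r$label else NA_integer_,
    integer(1))
  csf_labels <- csf_labels[!is.na(csf_labels)]
  ventricle <- array(as.integer(labels_flat %in% csf_labels), grid)

  list(dwi = dwi, labels = labels, truth = truth, wmh_prob = wmh_prob,
       ventricle = ventricle, wmh_mask = array(wmh_flat, grid),
       sigma_map = sigma_map, voxel_mm = phantom$voxel_mm)
}

# reject tensor pairs whose predicted signal is non-monotone over the shells
check_signal_monotone <- function(par, scheme) {
  dirs <- scheme$unique_directions
  b_max <- max(scheme$bvalues) / 1000
  ap <- apparent_along(par, dirs)
  # dS/db < 0 for b <= b_max requires K_app < 3 / (b_max * D_app)
  bad <- ap$K_app >= 3 / (b_max * ap$D_app) - 1e-12
  if (any(bad))
    stop("phantom spec rejected: predicted signal increases with b along ",
         sum(bad), " direction(s); kurtosis exceeds the model validity range ",
         "at b_max")
  invisible(TRUE)
}

#' Draw a random physically valid DKI voxel
#'
#' Samples a randomly rotated two-compartment Gaussian mixture (eigenvalues
#' in brain-typical ranges) and keeps only parameter sets whose apparent
#' kurtosis stays strictly inside the model validity range
#' `K_app < 3 / (b_max D_app)` on the scheme directions, so the voxel is
#' representable by the truncated signal model at the scheme's largest
#' b-value. Uses the caller's RNG stream.
#'
#' @param scheme a `gradient_table` defining the validity check.
#' @param s0_range range for the uniform S0 draw.
#' @param margin safety factor (< 1) applied to the kurtosis bound.
#' @return list with `S0`, `d6`, `w15`.
#' @export
random_dki_voxel <- function(scheme, s0_range = c(50, 150), margin = 0.95) {
  b_max <- max(scheme$bvalues) / 1000
  dirs <- scheme$unique_directions
  repeat {
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- quaternion_rotation(q)
    lam1 <- sort(stats::runif(3, 0.2, 2.0), decreasing = TRUE)
    lam2 <- sort(stats::runif(3, 0.1, 1.2), decreasing = TRUE)
    f <- stats::runif(1, 0.3, 0.7)
    mix <- kt_from_gaussian_mixture(
      list(R %*% diag(lam1) %*% t(R), R %*% diag(lam2) %*% t(R)),
      c(f, 1 - f))
    ap <- apparent_along(mix, dirs)
    if (all(ap$K_app < margin * 3 / (b_max * ap$D_app))) break
  }
  mix$S0 <- stats::runif(1, s0_range[1], s0_range[2])
  mix
}

quaternion_rotation <- function(q) {
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d), 2 * (b * d + a * cc),
    2 * (b * cc + a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d - a * b),
    2 * (b * d - a * cc), 2 * (cc * d + a * b), a^2 - b^2 - cc^2 + d^2
  ), 3, 3, byrow = TRUE)
}

#' Rician-corrupt a signal array
#'
#' Magnitude of `(S + N(0, sigma)) + i N(0, sigma)`. With `sigma = 0` the
#' input is returned unchanged.
#'
#' @param s numeric array/vector of noiseless magnitudes.
#' @param sigma Gaussian channel noise standard deviation.
#' @export
add_rician_noise <- function(s, sigma) {
  if (sigma == 0) return(s)
  sqrt((s + stats::rnorm(length(s), 0, sigma))^2 +
         stats::rnorm(length(s), 0, sigma)^2)
}
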