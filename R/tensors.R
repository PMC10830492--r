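# Tensor packing conventions used throughout:
#   D: 6 unique components in order (xx, yy, zz, xy, xz, yz), units um^2/ms
#      (= 10^-3 mm^2/s), so values near 1 for brain parenchyma.
#   W: 15 unique components of the fully symmetric rank-4 kurtosis tensor in
#      order (1111, 2222, 3333, 1112, 1113, 1222, 2223, 1333, 2333,
#             1122, 1133, 2233, 1123, 1223, 1233), dimensionless.

d6_index <- function() {
  cbind(i = c(1, 2, 3, 1, 1, 2), j = c(1, 2, 3, 2, 3, 3))
}

d6_mult <- function() c(1, 1, 1, 2, 2, 2)

w15_index <- function() {
  rbind(
    c(1, 1, 1, 1), c(2, 2, 2, 2), c(3, 3, 3, 3),
    c(1, 1, 1, 2), c(1, 1, 1, 3), c(1, 2, 2, 2), c(2, 2, 2, 3),
    c(1, 3, 3, 3), c(2, 3, 3, 3),
    c(1, 1, 2, 2), c(1, 1, 3, 3), c(2, 2, 3, 3),
    c(1, 1, 2, 3), c(1, 2, 2, 3), c(1, 2, 3, 3)
  )
}

w15_mult <- function() c(1, 1, 1, 4, 4, 4, 4, 4, 4, 6, 6, 6, 12, 12, 12)

#' Pack a symmetric 3x3 diffusion tensor into 6 unique components
#' @param mat symmetric 3x3 matrix.
#' @return numeric length-6 vector (xx, yy, zz, xy, xz, yz).
#' @export
dt_pack <- function(mat) {
  c(mat[1, 1], mat[2, 2], mat[3, 3], mat[1, 2], mat[1, 3], mat[2, 3])
}

#' Expand 6 unique diffusion-tensor components to a symmetric 3x3 matrix
#' @param d6 length-6 vector (xx, yy, zz, xy, xz, yz).
#' @export
dt_unpack <- function(d6) {
  matrix(c(d6[1], d6[4], d6[5],
           d6[4], d6[2], d6[6],
           d6[5], d6[6], d6[3]), 3, 3)
}

#' Expand 15 unique kurtosis-tensor components to the full 3x3x3x3 array
#' @param w15 length-15 vector in the package component order.
#' @export
kt_unpack <- function(w15) {
  arr <- array(0, c(3, 3, 3, 3))
  idx <- w15_index()
  for (r in seq_len(15)) {
    perms <- unique(perm4(idx[r, ]))
    for (p in seq_len(nrow(perms)))
      arr[perms[p, 1], perms[p, 2], perms[p, 3], perms[p, 4]] <- w15[r]
  }
  arr
}

#' Pack a fully symmetric 3x3x3x3 array into 15 unique components
#' @param arr a 3x3x3x3 array (symmetrised if not already symmetric).
#' @export
kt_pack <- function(arr) {
  arr <- kt_symmetrize(arr)
  idx <- w15_index()
  vapply(seq_len(15), function(r) arr[idx[r, 1], idx[r, 2], idx[r, 3], idx[r, 4]],
         numeric(1))
}

# average a rank-4 array over all 24 index permutations
kt_symmetrize <- function(arr) {
  perms <- perm4(1:4)
  out <- array(0, c(3, 3, 3, 3))
  for (p in seq_len(nrow(perms)))
    out <- out + aperm(arr, perms[p, ])
  out / nrow(perms)
}

# all permutations of a length-4 vector (24 rows)
perm4 <- function(v) {
  res <- matrix(0L, 24, 4)
  r <- 1L
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b))) {
    d <- setdiff(1:4, c(a, b, cc))
    res[r, ] <- c(v[a], v[b], v[cc], v[d])
    r <- r + 1L
  }
  res
}

# design rows mapping packed components to apparent values along directions:
# dir_design_d %*% d6 = D_app(n);  dir_design_w %*% w15 = sum_ijkl n n n n W
dir_design_d <- function(dirs) {
  cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
        2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
        2 * dirs[, 2] * dirs[, 3])
}

dir_design_w <- function(dirs) {
  idx <- w15_index()
  mult <- w15_mult()
  out <- matrix(0, nrow(dirs), 15)
  for (r in seq_len(15)) {
    out[, r] <- mult[r] * dirs[, idx[r, 1]] * dirs[, idx[r, 2]] *
      dirs[, idx[r, 3]] * dirs[, idx[r, 4]]
  }
  out
}

#' Apparent diffusivity and kurtosis along a direction
#'
#' For unit direction n, `D_app = n' D n` and
#' `K_app = (MD^2 / D_app^2) * sum_ijkl n_i n_j n_k n_l W_ijkl`.
#' Both are invariant to the sign of `n`.
#'
#' @param fit a `dki_fit` (or any list with `d6` and `w15` fields).
#' @param n unit direction vector, or a matrix of unit row vectors.
#' @return a list with `D_app` and `K_app` (vectors if `n` is a matrix).
#' @export
apparent_along <- function(fit, n) {
  if (is.null(dim(n))) n <- matrix(n, 1, 3)
  d_app <- drop(dir_design_d(n) %*% fit$d6)
  md <- mean(fit$d6[1:3])
  wsum <- drop(dir_design_w(n) %*% fit$w15)
  bad <- d_app <= 0
  k_app <- ifelse(bad, NA_real_, md^2 / d_app^2 * wsum)
  list(D_app = d_app, K_app = k_app, degenerate = any(bad))
}

#' Apparent kurtosis with second-order bias correction
#'
#' The directional kurtosis is the ratio `K_app = A / B^2` of two estimated
#' quantities (`A`: quartic contraction of the kurtosis block, `B`: apparent
#' diffusivity), whose estimation errors are correlated through the shared
#' design; the plug-in ratio therefore carries an O(sigma^2) bias. When the
#' fit provides a parameter covariance, a delta-method correction
#' `K + 2 cov(A, B)/B^3 - 3 A var(B)/B^4` removes the leading term.
#' Without a covariance this reduces to the plain ratio.
#'
#' @param fit a `dki_fit` (with optional `param_cov`).
#' @param dirs matrix of unit row vectors.
#' @return vector of (corrected) apparent kurtosis values.
#' @keywords internal
kapp_corrected <- function(fit, dirs) {
  ap <- apparent_along(fit, dirs)
  k <- ap$K_app
  if (is.null(fit$param_cov)) return(k)
  md <- mean(fit$d6[1:3])
  a_rows <- dir_design_w(dirs)                  # 15-column quartic design
  c_rows <- dir_design_d(dirs)                  # 6-column quadratic design
  A <- drop(a_rows %*% (fit$w15 * md^2))
  B <- ap$D_app
  S_vd <- fit$param_cov[8:22, 2:7, drop = FALSE]
  S_dd <- fit$param_cov[2:7, 2:7, drop = FALSE]
  cov_ab <- rowSums((a_rows %*% S_vd) * c_rows)
  var_b <- rowSums((c_rows %*% S_dd) * c_rows)
  # the expansion is only trustworthy when B is well determined; outside
  # that regime (relative SD of B above 20%) the correction is skipped, and
  # it is always capped at +/- 1 kurtosis unit
  ok <- is.finite(B) & B > 0.05 & var_b < 0.04 * B^2
  corr <- 2 * cov_ab[ok] / B[ok]^3 - 3 * A[ok] * var_b[ok] / B[ok]^4
  k[ok] <- k[ok] + pmin(pmax(corr, -1), 1)
  k
}

#' The isotropic rank-4 tensor scaled by a mean kurtosis level
#'
#' Returns the 15 unique components of `wbar * I4` where
#' `I4_ijkl = (d_ij d_kl + d_ik d_jl + d_il d_jk) / 3`; its apparent kurtosis
#' along any direction with an isotropic D equals `wbar`.
#'
#' @param wbar scalar level.
#' @export
isotropic_w <- function(wbar = 1) {
  wbar * c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1 / 3, 1 / 3, 1 / 3, 0, 0, 0)
}

#' Diffusion and kurtosis tensors of a Gaussian-compartment mixture
#'
#' A mixture of Gaussian compartments with tensors `Ds` and weights
#' `fractions` has overall tensor `D = sum f_c D_c` and kurtosis tensor
#' `W = (3 / MD^2) * sym( sum f_c D_c (x) D_c - D (x) D )`, which is
#' guaranteed to produce non-negative apparent kurtosis in every direction.
#' This is the package's generator of physically valid ground-truth tensor
#' pairs.
#'
#' @param Ds list of symmetric 3x3 compartment tensors (um^2/ms).
#' @param fractions mixture weights (summing to 1).
#' @return list with `d6` and `w15`.
#' @export
kt_from_gaussian_mixture <- function(Ds, fractions) {
  stopifnot(length(Ds) == length(fractions), abs(sum(fractions) - 1) < 1e-8)
  dbar <- Reduce(`+`, Map(function(D, f) f * D, Ds, fractions))
  m <- array(0, c(3, 3, 3, 3))
  for (cix in seq_along(Ds)) {
    D <- Ds[[cix]]
    m <- m + fractions[cix] * outer(D, D)
  }
  m <- m - outer(dbar, dbar)
  md <- mean(diag(dbar))
  w_full <- kt_symmetrize(3 / md^2 * m)
  list(d6 = dt_pack(dbar), w15 = kt_pack(w_full))
}

#' Rescale a kurtosis tensor to a target mean kurtosis
#'
#' `K_app` is linear in W, so multiplying W by a constant rescales MK exactly.
#'
#' @param d6,w15 packed tensors.
#' @param dirs direction set over which MK is averaged.
#' @param target_mk desired mean kurtosis.
#' @return the rescaled `w15`.
#' @export
scale_w_to_mk <- function(d6, w15, dirs, target_mk) {
  cur <- mean(apparent_along(list(d6 = d6, w15 = w15), dirs)$K_app)
  if (abs(cur) < 1e-12) stop("current MK is zero; cannot rescale")
  w15 * target_mk / cur
}

#' Derive the eight scalar diffusion and kurtosis metrics from a tensor fit
#'
#' Diffusion-tensor metrics come from the eigen-system of D (eigenvalues
#' sorted descending): MD = mean eigenvalue, D_axial = lambda1,
#' D_radial = (lambda2 + lambda3)/2, and FA is the usual normalised
#' eigenvalue dispersion. Kurtosis metrics are directional averages of
#' `K_app`: MK over `mk_dirs` (the acquisition directions by default,
#' or a dense 256-direction set), K_axial along the principal eigenvector,
#' K_radial averaged over `m_radial` azimuths perpendicular to it. KFA is the
#' Frobenius-norm anisotropy of W relative to its isotropic part,
#' `||W - Wbar I4||_F / ||W||_F`, with
#' `Wbar = (W1111 + W2222 + W3333 + 2 W1122 + 2 W1133 + 2 W2233) / 5`,
#' defined as 0 when W vanishes.
#'
#' @param fit a `dki_fit` (or list with `d6`, `w15`).
#' @param scheme a `gradient_table` supplying the acquisition directions.
#' @param mk_dirs `"acquisition"` (default) or `"dense"`.
#' @param m_radial number of azimuths for the radial-kurtosis average.
#' @return a named list of class `metric_set`: MD, D_axial, D_radial
#'   (um^2/ms = 10^-3 mm^2/s), FA, KFA, MK, K_axial, K_radial
#'   (dimensionless), plus `lambda` and `evec`.
#' @export
compute_metrics <- function(fit, scheme, mk_dirs = c("acquisition", "dense"),
                            m_radial = 64L) {
  mk_dirs <- match.arg(mk_dirs)
  if (any(!is.finite(c(fit$d6, fit$w15)))) {
    nas <- rep(NA_real_, 1)
    return(structure(list(MD = nas, D_axial = nas, D_radial = nas, FA = nas,
                          KFA = nas, MK = nas, K_axial = nas, K_radial = nas,
                          lambda = rep(NA_real_, 3), evec = matrix(NA_real_, 3, 3),
                          valid = FALSE),
                     class = "metric_set"))
  }
  es <- eigen(dt_unpack(fit$d6), symmetric = TRUE)
  lam <- es$values            # descending
  md <- mean(lam)
  d_ax <- lam[1]
  d_rad <- (lam[2] + lam[3]) / 2
  denom <- sqrt(sum(lam^2))
  fa <- if (denom < 1e-15) 0 else
    sqrt(1.5 * sum((lam - md)^2)) / denom
  dirset <- if (mk_dirs == "acquisition") scheme$unique_directions else
    dense_sphere_directions()
  mk <- mean(kapp_corrected(fit, dirset))
  e1 <- es$vectors[, 1]
  k_ax <- kapp_corrected(fit, matrix(e1, 1, 3))
  k_rad <- mean(kapp_corrected(fit, perpendicular_circle(e1, m_radial)))
  structure(
    list(MD = md, D_axial = d_ax, D_radial = d_rad, FA = fa,
         KFA = kfa(fit$w15), MK = mk, K_axial = k_ax, K_radial = k_rad,
         lambda = lam, evec = es$vectors, valid = TRUE),
    class = "metric_set"
  )
}

#' @export
print.metric_set <- function(x, ...) {
  v <- unlist(x[metric_names()])
  cat("DKI metrics:\n")
  print(round(v, 4))
  invisible(x)
}

#' Canonical metric names, in reporting order
#' @export
metric_names <- function() {
  c("MK", "K_axial", "K_radial", "KFA", "MD", "D_axial", "D_radial", "FA")
}

#' Kurtosis fractional anisotropy of a packed kurtosis tensor
#'
#' @param w15 packed kurtosis tensor.
#' @return KFA in [0, 1]; 0 when the tensor vanishes.
#' @export
kfa <- function(w15) {
  wfull <- kt_unpack(w15)
  nrm <- sqrt(sum(wfull^2))
  if (nrm < 1e-15) return(0)
  wbar <- (w15[1] + w15[2] + w15[3] + 2 * (w15[10] + w15[11] + w15[12])) / 5
  iso <- kt_unpack(isotropic_w(wbar))
  sqrt(sum((wfull - iso)^2)) / nrm
}

dense_sphere_env <- new.env()

# cached deterministic 256-direction set for dense MK averaging
dense_sphere_directions <- function(n = 256L) {
  key <- paste0("d", n)
  if (is.null(dense_sphere_env[[key]]))
    dense_sphere_env[[key]] <- repulsion_directions(n, seed = 7L, n_iter = 150L)
  dense_sphere_env[[key]]
}

#' Rotate a packed tensor pair by a rotation matrix
#'
#' @param d6,w15 packed tensors.
#' @param R a 3x3 rotation matrix.
#' @return list with rotated `d6` and `w15`.
#' @export
rotate_tensors <- function(d6, w15, R) {
  dmat <- R %*% dt_unpack(d6) %*% t(R)
  w <- kt_unpack(w15)
  # contract each of the four slots with R in turn
  for (slot in 1:4) {
    w <- aperm(w, c(slot, setdiff(1:4, slot)))
    dim(w) <- c(3, 27)
    w <- R %*% w
    dim(w) <- c(3, 3, 3, 3)
    w <- aperm(w, order(c(slot, setdiff(1:4, slot))))
  }
  list(d6 = dt_pack(dmat), w15 = kt_pack(w))
}
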