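#' Design matrix of the linearised two-shell DKI model
#'
#' The log-signal model is `log S = log S0 - b D_app(n) + (b^2/6) D_app^2 K_app`,
#' which is linear in the 22 parameters
#' `[log S0, D (6 components), MD^2 W (15 components)]`:
#' each row is `[1, -b * a(n), (b^2/6) * w(n)]` where `a(n)` carries the
#' quadratic direction products with off-diagonal multiplicity 2 and `w(n)`
#' the quartic products with multiplicities 4/6/12. b0 rows reduce to the
#' intercept. Internally b is scaled to ms/um^2 (b/1000) so the diffusion
#' block is estimated directly in um^2/ms.
#'
#' A single non-zero shell cannot separate the diffusion and kurtosis blocks
#' (the b and b^2 columns are proportional), so at least two shells are
#' required.
#'
#' @param scheme a `gradient_table`.
#' @return a (volumes x 22) matrix.
#' @export
build_design_matrix <- function(scheme) {
  b <- scheme$bvalues / 1000   # ms/um^2
  shells <- unique(b[b > 0])
  if (length(shells) < 2)
    stop("kurtosis block is rank-deficient: at least two non-zero shells ",
         "are required to separate diffusion and kurtosis terms")
  dirs <- scheme$directions
  cbind(1, -b * dir_design_d(dirs), (b^2 / 6) * dir_design_w(dirs))
}

# design matrix allowing degenerate schemes (used for b0-only edge checks)
design_matrix_unchecked <- function(scheme) {
  b <- scheme$bvalues / 1000
  cbind(1, -b * dir_design_d(scheme$directions),
        (b^2 / 6) * dir_design_w(scheme$directions))
}

#' Default DKI fitting configuration
#'
#' @param reweight_passes reweighting passes of the linear initialisation
#'   (weights = squared predicted signal, stabilising log-domain
#'   heteroscedasticity).
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @param constrained apply the post-fit constraint projection.
#' @param k_min,c_max apparent-kurtosis bounds: `K_app` is constrained to
#'   `[k_min, c_max / (b_max * D_app)]` on the scheme directions. The upper
#'   bound is the standard validity limit of the truncated cumulant
#'   expansion; the lower bound -3/7 is the conventional minimum apparent
#'   kurtosis (a hard zero floor truncates the noise distribution of
#'   kurtosis-free tissue and biases its mean kurtosis upward).
#' @param rician_correct compensate the magnitude-MRI noise floor by the
#'   method of moments, `S = sqrt(max(M^2 - 2 sigma^2, 0))`, with `sigma`
#'   taken from `noise_sigma` or estimated from the first-pass fit
#'   residuals; the corrected signals are then refit.
#' @param noise_sigma known noise standard deviation (`NULL` = estimate).
#' @param lambda_floor eigenvalue floor for D (um^2/ms) ensuring `D_app > 0`.
#' @export
dki_fit_config <- function(reweight_passes = 2L, max_iter = 100L,
                           constrained = TRUE, k_min = -3 / 7, c_max = 3,
                           rician_correct = TRUE, noise_sigma = NULL,
                           lambda_floor = 1e-6) {
  list(reweight_passes = reweight_passes, max_iter = max_iter,
       constrained = constrained, k_min = k_min, c_max = c_max,
       rician_correct = rician_correct, noise_sigma = noise_sigma,
       lambda_floor = lambda_floor)
}

#' Fit the DKI model in one voxel
#'
#' Three stages: (1) weighted linear least squares on log-signals, with
#' `reweight_passes` reweighting iterations using the squared predicted
#' signal as weights; (2) Levenberg-Marquardt refinement of all 22 parameters
#' on the signal-domain model `S = exp(X beta)`; (3) constraint projection
#' (non-negative diffusion eigenvalues; apparent kurtosis clipped to its
#' validity range on the scheme directions, with W refit by linear least
#' squares to the clipped values).
#'
#' If the LM step fails to improve the residual it is discarded in favour of
#' the linear solution (flagged in the diagnostics). Voxels with non-positive
#' b0 signal are flagged invalid (background).
#'
#' @param signals numeric vector of per-volume signals.
#' @param scheme a `gradient_table`.
#' @param config list from [dki_fit_config()].
#' @return an object of class `dki_fit`: `S0`, `d6`, `w15`, `valid`, and
#'   `diagnostics` (residual norms, iterations, convergence and
#'   constraint-activity flags).
#' @export
fit_dki_voxel <- function(signals, scheme, config = dki_fit_config()) {
  stopifnot(length(signals) == n_volumes(scheme))
  b0_idx <- which(scheme$bvalues == 0)
  if (length(b0_idx) > 0 && mean(signals[b0_idx]) <= 0)
    return(invalid_fit("non-positive b0 signal"))
  if (any(!is.finite(signals)))
    return(invalid_fit("non-finite signal"))
  X <- build_design_matrix(scheme)
  n_par <- ncol(X)

  est <- estimate_beta(signals, X, config)
  sigma2 <- if (!is.null(config$noise_sigma)) config$noise_sigma^2 else
    est$rss / (length(signals) - n_par)
  if (isTRUE(config$rician_correct) && sigma2 > 0) {
    # magnitude noise floor: E[M^2] = S^2 + 2 sigma^2; corrected signals are
    # floored at a fraction of sigma so the log-domain initialisation stays
    # bounded where the measurement is pure noise
    corrected <- pmax(sqrt(pmax(signals^2 - 2 * sigma2, 0)),
                      0.2 * sqrt(sigma2))
    est <- estimate_beta(corrected, X, config)
    if (is.null(config$noise_sigma))
      sigma2 <- est$rss / (length(signals) - n_par)
  }
  beta <- est$beta

  # parameter covariance from the signal-domain Jacobian (used downstream
  # for the second-order kurtosis bias correction)
  J <- as.vector(exp(X %*% beta)) * X
  param_cov <- tryCatch(sigma2 * chol2inv(chol(crossprod(J))),
                        error = function(e) sigma2 * MASS::ginv(crossprod(J)))

  s0 <- exp(beta[1])
  d6 <- beta[2:7]
  md <- mean(d6[1:3])
  w15 <- if (abs(md) < 1e-12) rep(0, 15) else beta[8:22] / md^2

  flags <- c(d_clamped = FALSE, k_clipped = FALSE,
             lm_rejected = !est$lm_ok)
  if (config$constrained) {
    proj <- project_constraints(d6, w15, scheme, config)
    d6 <- proj$d6; w15 <- proj$w15
    flags["d_clamped"] <- proj$d_clamped
    flags["k_clipped"] <- proj$k_clipped
  }
  structure(
    list(S0 = s0, d6 = d6, w15 = w15, valid = TRUE,
         param_cov = param_cov, sigma = sqrt(max(sigma2, 0)),
         diagnostics = list(rss_linear = est$rss_lin, rss = est$rss,
                            iterations = est$iterations,
                            converged = est$converged, flags = flags)),
    class = "dki_fit"
  )
}

# weighted linear initialisation + Levenberg-Marquardt refinement
estimate_beta <- function(signals, X, config) {
  s <- pmax(signals, 1e-10)
  logs <- log(s)
  beta <- qr.coef(qr(X), logs)
  for (pass in seq_len(config$reweight_passes)) {
    w <- exp(X %*% beta)^2
    sw <- sqrt(as.vector(w))
    beta <- qr.coef(qr(X * sw), logs * sw)
  }
  rss_lin <- sum((exp(X %*% beta) - signals)^2)

  resid_fn <- function(p) as.vector(exp(X %*% p)) - signals
  jac_fn <- function(p) as.vector(exp(X %*% p)) * X
  lm_ok <- TRUE
  fit <- tryCatch(
    minpack.lm::nls.lm(par = as.vector(beta), fn = resid_fn, jac = jac_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = config$max_iter)),
    error = function(e) NULL
  )
  iterations <- 0L
  converged <- FALSE
  if (!is.null(fit)) {
    rss_lm <- sum(fit$fvec^2)
    iterations <- fit$niter
    converged <- fit$info %in% 1:4
    if (rss_lm <= rss_lin + 1e-12) beta <- fit$par else lm_ok <- FALSE
  } else lm_ok <- FALSE
  rss <- sum((exp(X %*% beta) - signals)^2)
  list(beta = beta, rss = rss, rss_lin = rss_lin, iterations = iterations,
       converged = converged, lm_ok = lm_ok)
}

invalid_fit <- function(reason) {
  structure(
    list(S0 = NA_real_, d6 = rep(NA_real_, 6), w15 = rep(NA_real_, 15),
         valid = FALSE,
         diagnostics = list(rss_linear = NA_real_, rss = NA_real_,
                            iterations = 0L, converged = FALSE,
                            flags = c(d_clamped = FALSE, k_clipped = FALSE,
                                      lm_rejected = FALSE),
                            reason = reason)),
    class = "dki_fit"
  )
}

#' @export
print.dki_fit <- function(x, ...) {
  if (!x$valid) { cat("Invalid DKI fit (", x$diagnostics$reason, ")\n"); return(invisible(x)) }
  cat("DKI voxel fit: S0 =", signif(x$S0, 4),
      " MD =", signif(mean(x$d6[1:3]), 4), "um^2/ms\n")
  cat("  RSS", signif(x$diagnostics$rss, 4), "after",
      x$diagnostics$iterations, "LM iterations\n")
  invisible(x)
}

# clamp D eigenvalues, then project W onto the convex polytope
# { k_min <= K_app(n) <= c_max / (b_max * D_app(n)) on scheme directions }
# by exact Euclidean projection (Hildreth dual coordinate ascent)
project_constraints <- function(d6, w15, scheme, config) {
  es <- eigen(dt_unpack(d6), symmetric = TRUE)
  d_clamped <- any(es$values < config$lambda_floor)
  if (d_clamped) {
    lam <- pmax(es$values, config$lambda_floor)
    d6 <- dt_pack(es$vectors %*% diag(lam) %*% t(es$vectors))
  }
  dirs <- scheme$unique_directions
  md <- mean(d6[1:3])
  d_app <- drop(dir_design_d(dirs) %*% d6)
  b_max <- max(scheme$bvalues) / 1000
  # constraints are linear in w15: lo_d <= Wd w <= hi_d per direction
  Wd <- dir_design_w(dirs)
  hi <- (config$c_max / (b_max * d_app)) * d_app^2 / md^2
  lo <- config$k_min * d_app^2 / md^2
  v0 <- drop(Wd %*% w15)
  violated <- any(v0 < lo - 1e-12) || any(v0 > hi + 1e-12)
  if (violated) {
    # least-squares projection in the apparent-kurtosis metric: minimise
    # ||Wd (w - w0)||^2 subject to the directional bounds, via a change of
    # variables z = R w (R'R = Wd'Wd) and Hildreth's method in z
    R <- chol(crossprod(Wd))
    Rinv <- backsolve(R, diag(ncol(Wd)))
    A <- rbind(Wd, -Wd) %*% Rinv
    z <- project_polytope(drop(R %*% w15), A, c(hi, -lo))
    w15 <- drop(Rinv %*% z)
    # the dual iteration can stall on near-degenerate fits; W = 0 is always
    # feasible (lo <= 0 <= hi), so shrinking toward it guarantees feasibility
    v <- drop(Wd %*% w15)
    if (any(v < lo - 1e-9) || any(v > hi + 1e-9)) {
      t_hi <- ifelse(v > hi, hi / v, 1)
      t_lo <- ifelse(v < lo, lo / v, 1)
      w15 <- max(0, min(t_hi, t_lo, 1)) * w15
    }
  }
  list(d6 = d6, w15 = w15, d_clamped = d_clamped, k_clipped = violated)
}

# Euclidean projection of x0 onto { x : A x <= b } by Hildreth's method
project_polytope <- function(x0, A, b, max_pass = 500L, tol = 1e-12) {
  m <- nrow(A)
  nrm2 <- rowSums(A^2)
  lambda <- numeric(m)
  x <- x0
  for (pass in seq_len(max_pass)) {
    delta_max <- 0
    for (i in seq_len(m)) {
      if (nrm2[i] < 1e-300) next
      step <- (sum(A[i, ] * x) - b[i]) / nrm2[i]
      new_l <- max(0, lambda[i] + step)
      d <- new_l - lambda[i]
      if (d != 0) {
        x <- x - d * A[i, ]
        lambda[i] <- new_l
        delta_max <- max(delta_max, abs(d) * sqrt(nrm2[i]))
      }
    }
    if (delta_max < tol) break
  }
  x
}

#' Predict model signals for a parameter set
#'
#' `S(b, n) = S0 exp(-b D_app + b^2 D_app^2 K_app / 6)` evaluated for every
#' volume of the scheme.
#'
#' @param fit a `dki_fit` or list with `S0`, `d6`, `w15`.
#' @param scheme a `gradient_table`.
#' @return numeric vector of per-volume signals.
#' @export
predict_signals <- function(fit, scheme) {
  b <- scheme$bvalues / 1000
  ap <- apparent_along(fit, scheme$directions)
  d_app <- ap$D_app
  k_app <- ifelse(is.na(ap$K_app), 0, ap$K_app)
  as.vector(fit$S0 * exp(-b * d_app + b^2 * d_app^2 * k_app / 6))
}

#' Fit the DKI model over a masked 4-D volume
#'
#' Applies [fit_dki_voxel()] to every voxel inside `mask` and assembles the
#' eight scalar metric maps plus a diagnostic map. Outside-mask and invalid
#' voxels carry `NA`.
#'
#' @param dwi 4-D array (x, y, z, volume).
#' @param scheme a `gradient_table`.
#' @param mask logical/0-1 3-D array; `NULL` fits every voxel.
#' @param config from [dki_fit_config()].
#' @param mk_dirs direction set for MK averaging, see [compute_metrics()].
#' @return list with `metrics` (named list of eight 3-D arrays), `valid`
#'   (logical 3-D array), and `diagnostics` (3-D array of LM iteration
#'   counts, NA outside mask).
#' @export
fit_volume <- function(dwi, scheme, mask = NULL, config = dki_fit_config(),
                       mk_dirs = "acquisition") {
  dm <- dim(dwi)
  if (length(dm) != 4) stop("dwi must be a 4-D array")
  if (dm[4] != n_volumes(scheme)) stop("volume count does not match scheme")
  grid <- dm[1:3]
  if (is.null(mask)) mask <- array(TRUE, grid)
  if (!all(dim(mask) == grid)) stop("mask grid does not match dwi grid")
  mask <- array(as.logical(mask), grid)
  maps <- setNames(
    lapply(metric_names(), function(nm) array(NA_real_, grid)),
    metric_names()
  )
  valid <- array(FALSE, grid)
  diag_map <- array(NA_real_, grid)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
      f <- fit_dki_voxel(dwi[i, j, k, ], scheme, config)
      diag_map[i, j, k] <- f$diagnostics$iterations
      if (!f$valid) next
      m <- compute_metrics(f, scheme, mk_dirs = mk_dirs)
      if (!isTRUE(m$valid)) next
      valid[i, j, k] <- TRUE
      for (nm in metric_names()) maps[[nm]][i, j, k] <- m[[nm]]
    }
  }
  list(metrics = maps, valid = valid, diagnostics = diag_map)
}
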