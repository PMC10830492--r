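test_that("design matrix has full rank 22 on the default scheme (SVD oracle)", {
  X <- build_design_matrix(default_scheme)
  expect_equal(dim(X), c(65, 22))
  sv <- svd(X)$d
  expect_equal(sum(sv > max(sv) * 1e-10), 22)
})

test_that("b0 rows reduce to the intercept and kurtosis block scales with b^2", {
  X <- build_design_matrix(default_scheme)
  b0_rows <- which(default_scheme$bvalues == 0)
  for (r in b0_rows) expect_equal(unname(X[r, ]), c(1, rep(0, 21)))
  # same direction at b = 1000 and b = 2000: kurtosis entries scale 4x
  i1 <- which(default_scheme$bvalues == 1000)[1]
  i2 <- which(default_scheme$bvalues == 2000)[1]
  expect_equal(default_scheme$directions[i1, ], default_scheme$directions[i2, ])
  expect_equal(X[i2, 8:22], 4 * X[i1, 8:22])
  expect_equal(X[i2, 2:7], 2 * X[i1, 2:7])
})

test_that("single-shell schemes are rejected with a kurtosis rank message", {
  sch <- suppressWarnings(build_scheme(30, 1000, 5))
  expect_error(build_design_matrix(sch), "kurtosis")
})

test_that("noiseless cigar voxel with MK = 0.9 is recovered to 1e-5", {
  s <- predict_signals(cigar_truth, default_scheme)
  f <- fit_dki_voxel(s, default_scheme)
  m <- compute_metrics(f, default_scheme)
  expect_equal(m$MK, 0.9, tolerance = 1e-5)
  expect_equal(f$d6, cigar_truth$d6, tolerance = 1e-6)
  expect_equal(f$S0, 100, tolerance = 1e-6)
})

test_that("isotropic Gaussian voxel fits to zero kurtosis and zero FA", {
  par <- list(S0 = 80, d6 = dt_pack(diag(3) * 1.0), w15 = rep(0, 15))
  s <- predict_signals(par, default_scheme)
  f <- fit_dki_voxel(s, default_scheme)
  m <- compute_metrics(f, default_scheme)
  expect_lt(abs(m$MK), 1e-6)
  expect_lt(abs(m$K_axial), 1e-6)
  expect_lt(abs(m$K_radial), 1e-6)
  expect_lt(m$FA, 1e-6)
})

test_that("random valid voxels are recovered at machine-level accuracy without noise", {
  set.seed(21)
  for (k in 1:50) {
    truth <- random_valid_voxel()
    s <- predict_signals(truth, default_scheme)
    f <- fit_dki_voxel(s, default_scheme)
    rel_d <- abs(f$d6 - truth$d6) / max(abs(truth$d6))
    expect_lt(max(rel_d), 1e-4)
    expect_lt(abs(f$S0 - truth$S0) / truth$S0, 1e-6)
    expect_lt(max(abs(f$w15 - truth$w15)) / max(abs(truth$w15), 1e-6), 1e-4)
  }
})

test_that("LM refinement never increases the signal-domain residual", {
  set.seed(22)
  for (k in 1:30) {
    truth <- random_valid_voxel()
    s <- predict_signals(truth, default_scheme)
    noisy <- add_rician_noise(s, truth$S0 / 20)
    f <- fit_dki_voxel(noisy, default_scheme)
    expect_lte(f$diagnostics$rss, f$diagnostics$rss_linear + 1e-9)
  }
})

test_that("background voxels are flagged invalid rather than fit", {
  s <- rep(0, n_volumes(default_scheme))
  f <- fit_dki_voxel(s, default_scheme)
  expect_false(f$valid)
  expect_true(all(is.na(f$d6)))
})

test_that("constraint projection clips apparent kurtosis into its validity range", {
  # corrupt signals strongly to provoke constraint violations
  set.seed(23)
  n_clipped <- 0
  for (k in 1:20) {
    truth <- random_valid_voxel()
    s <- predict_signals(truth, default_scheme)
    noisy <- add_rician_noise(s, truth$S0 / 5)   # very low SNR
    f <- fit_dki_voxel(noisy, default_scheme)
    if (!f$valid) next
    ap <- apparent_along(f, default_scheme$unique_directions)
    b_max <- max(default_scheme$bvalues) / 1000
    expect_true(all(ap$K_app >= -3 / 7 - 1e-5))
    expect_true(all(ap$K_app <= 3 / (b_max * ap$D_app) + 1e-5))
    lam <- eigen(dt_unpack(f$d6), symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(lam >= 0))
    n_clipped <- n_clipped + f$diagnostics$flags["k_clipped"]
  }
  expect_gt(n_clipped, 0)  # the scenario actually exercises the projection
})

test_that("fit_volume matches per-voxel fits and handles masks", {
  sch <- default_scheme
  ph <- phantom_spec(grid = c(4, 4, 4), snr = Inf, seed = 2)
  sim <- simulate_dwi(ph, sch)
  fv <- fit_volume(sim$dwi, sch)
  # ground-truth agreement
  for (nm in metric_names())
    expect_lt(max(abs(fv$metrics[[nm]] - sim$truth[[nm]]), na.rm = TRUE), 1e-4)
  # locality: masked run agrees voxel-for-voxel on the mask interior
  mask <- array(FALSE, c(4, 4, 4)); mask[1:2, 1, 1] <- TRUE
  fm <- fit_volume(sim$dwi, sch, mask)
  expect_equal(fm$metrics$MK[mask], fv$metrics$MK[mask])
  expect_true(all(is.na(fm$metrics$MK[!mask])))
  # single-voxel fit identical to volume result
  f1 <- fit_dki_voxel(sim$dwi[1, 1, 1, ], sch)
  m1 <- compute_metrics(f1, sch)
  expect_equal(fv$metrics$MK[1, 1, 1], m1$MK)
  # empty mask: all missing, no error
  fe <- fit_volume(sim$dwi, sch, array(FALSE, c(4, 4, 4)))
  expect_true(all(is.na(fe$metrics$MK)))
  # grid mismatch
  expect_error(fit_volume(sim$dwi, sch, array(TRUE, c(3, 4, 4))), "grid")
})
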