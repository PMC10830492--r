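test_that("lesion thresholding reproduces hand-computed volumes", {
  # 1000 voxels at prob 0.9 in a 10x10x10 grid, 2.5 mm isotropic
  pm <- array(0.9, c(10, 10, 10))
  out <- threshold_wmh(pm, 0.5, voxel_mm = 2.5)
  expect_equal(out$volume_ml, 1000 * 15.625 / 1000)
  expect_true(all(out$mask))
  # all below threshold: empty mask, zero volume
  out2 <- threshold_wmh(array(0.4, c(5, 5, 5)), 0.5)
  expect_equal(out2$volume_ml, 0)
  expect_false(any(out2$mask))
  # boundary: >= by default, > when strict
  pm3 <- array(0.5, c(2, 2, 2))
  expect_equal(sum(threshold_wmh(pm3, 0.5)$mask), 8)
  expect_equal(sum(threshold_wmh(pm3, 0.5, strict = TRUE)$mask), 0)
})

test_that("lesion volume is non-increasing in the threshold", {
  set.seed(41)
  pm <- array(runif(8 * 8 * 8), c(8, 8, 8))
  vols <- sapply(seq(0.1, 0.9, by = 0.1),
                 function(t) threshold_wmh(pm, t)$volume_ml)
  expect_true(all(diff(vols) <= 0))
})

test_that("probability maps outside [0, 1] are rejected", {
  expect_error(threshold_wmh(array(1.2, c(2, 2, 2))), "outside")
  expect_error(threshold_wmh(array(-0.1, c(2, 2, 2))), "outside")
})

test_that("default region sets have 16 white-matter and 14 thalamic entries", {
  wm <- wm_region_names()
  th <- thalamic_region_names()
  expect_equal(nrow(wm), 16)
  expect_equal(nrow(th), 14)
  expect_equal(sort(unique(wm$hemisphere)), c("L", "R"))
  expect_equal(length(unique(wm$abbrev)), 8)
  expect_equal(length(unique(th$abbrev)), 7)
  expect_true(all(wm$compartment == "WM"))
  expect_true(all(th$compartment == "THA"))
  expect_equal(length(intersect(wm$label, th$label)), 0)
})

test_that("regional means on a 4x4x4 toy match hand computation", {
  grid <- c(4, 4, 4)
  vol <- array(0L, grid)
  vol[1:2, , ] <- 1L   # 32 voxels
  vol[3:4, , ] <- 2L   # 32 voxels
  names <- data.frame(label = 1:2, abbrev = c("A", "B"),
                      name = c("regA", "regB"), hemisphere = c("L", "R"),
                      compartment = "WM")
  atlas <- label_atlas(vol, names, voxel_mm = 2)
  mk <- array(0, grid)
  mk[vol == 1L] <- 1.0
  mk[vol == 2L] <- 2.0
  mk[1, 1, 1] <- 5.0          # an outlier we will exclude via WMH
  wmh <- array(FALSE, grid); wmh[1, 1, 1] <- TRUE
  vent <- array(FALSE, grid); vent[3, 1, 1] <- TRUE
  rt <- regional_means(list(MK = mk), atlas, wmh, vent)
  a <- rt[rt$region == "A", ]
  b <- rt[rt$region == "B", ]
  expect_equal(a$n_total, 32); expect_equal(a$n_excluded_wmh, 1)
  expect_equal(a$n_used, 31);  expect_equal(a$mean, 1.0)
  expect_equal(b$n_excluded_ventricle, 1)
  expect_equal(b$n_used, 31);  expect_equal(b$mean, 2.0)
  expect_equal(a$n_used, a$n_total - a$n_excluded_wmh - a$n_excluded_ventricle)
  # without masks: the outlier shifts region A upward
  rt0 <- regional_means(list(MK = mk), atlas)
  expect_equal(rt0[rt0$region == "A", "mean"], (31 * 1 + 5) / 32)
  expect_gt(rt0[rt0$region == "A", "mean"], a$mean)
})

test_that("exclusion masks only ever remove voxels", {
  set.seed(42)
  grid <- c(6, 6, 6)
  atlas <- synthetic_label_atlas(grid, wm_region_names())
  mk <- array(runif(prod(grid)), grid)
  wmh <- array(runif(prod(grid)) < 0.2, grid)
  rt_m <- regional_means(list(MK = mk), atlas, wmh)
  rt_0 <- regional_means(list(MK = mk), atlas)
  expect_true(all(rt_m$n_used <= rt_0$n_used))
})

test_that("lesion exclusion raises regional MK when lesions carry low MK", {
  # construction: lesion voxels have MK 0.3, tissue 1.0
  grid <- c(6, 6, 6)
  atlas <- synthetic_label_atlas(grid, wm_region_names())
  set.seed(43)
  wmh <- array(runif(prod(grid)) < 0.3, grid)
  mk <- array(1.0, grid); mk[wmh] <- 0.3
  with_excl <- regional_means(list(MK = mk), atlas, wmh)
  without <- regional_means(list(MK = mk), atlas)
  hit <- without$n_excluded_wmh >= 0 & with_excl$n_used > 0 &
    without$mean < 1.0   # regions actually containing lesions
  expect_gt(sum(hit), 0)
  expect_true(all(with_excl$mean[hit] > without$mean[hit]))
  # inversion mode measures inside the lesions instead
  inside <- regional_means(list(MK = mk), atlas, wmh, invert_wmh = TRUE)
  ok <- inside$valid
  expect_true(all(abs(inside$mean[ok] - 0.3) < 1e-12))
})

test_that("lesion voxel bookkeeping conserves the thresholded volume", {
  grid <- c(6, 6, 6)
  set.seed(44)
  pm <- array(runif(prod(grid)), grid)
  th <- threshold_wmh(pm, 0.5, voxel_mm = 2.5)
  mask_atlas <- array(FALSE, grid); mask_atlas[2:5, , ] <- TRUE
  atlas <- synthetic_label_atlas(grid, wm_region_names(), mask = mask_atlas)
  rt <- regional_means(list(MK = array(1, grid)), atlas, th$mask)
  inside <- sum(rt$n_excluded_wmh) / length(unique(rt$metric))
  outside <- sum(th$mask & atlas$volume == 0)
  expect_equal(inside + outside, sum(th$mask))
})

test_that("feature aggregation reproduces hand-worked averages and counts", {
  tb <- data.frame(
    subject = "s1",
    label = c(1, 2, 3, 4), region = c("A", "A", "B", "B"),
    hemisphere = c("L", "R", "L", "R"), compartment = "WM",
    metric = "MK", mean = c(0.8, 1.0, 0.6, NA),
    n_total = 10, n_excluded_wmh = 0, n_excluded_ventricle = 0,
    n_used = c(10, 10, 10, 0), valid = c(TRUE, TRUE, TRUE, FALSE)
  )
  class(tb) <- c("region_table", "data.frame")
  per <- aggregate_features(tb, "per-region")
  expect_equal(per$A_L_MK, 0.8)
  expect_true(is.na(per$B_R_MK))
  hemi <- aggregate_features(tb, "hemisphere-average")
  expect_equal(hemi$A_MK, 0.9)
  expect_equal(hemi$B_MK, 0.6)    # invalid R side omitted
  comp <- aggregate_features(tb, "compartment-average")
  expect_equal(comp$WM_MK, mean(c(0.8, 1.0, 0.6)))  # 3 valid regions
  expect_equal(unname(attr(comp, "n_regions_used")["s1"]), 3)
  # all-invalid subject errors with its name
  tb$valid <- FALSE
  expect_error(aggregate_features(tb, "compartment-average"), "s1")
})

test_that("a triple-metric bilateral white-matter block spans 48 features", {
  co <- small_cohort(seed = 45)
  cols <- feature_columns(co, c("MK", "K_radial", "FA"), "WM")
  expect_equal(length(cols), 48)
})

test_that("feature assembly is invariant to subject ordering", {
  grid <- c(6, 6, 6)
  atlas <- synthetic_label_atlas(grid, wm_region_names())
  set.seed(46)
  rts <- lapply(c("s1", "s2"), function(s)
    regional_means(list(MK = array(runif(prod(grid)), grid)), atlas,
                   subject = s))
  fwd <- aggregate_features(rbind(rts[[1]], rts[[2]]), "per-region")
  rev <- aggregate_features(rbind(rts[[2]], rts[[1]]), "per-region")
  expect_equal(fwd[order(fwd$subject), -1], rev[order(rev$subject), -1],
               ignore_attr = TRUE)
})
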