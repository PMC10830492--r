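test_that("widely separated 1-D groups classify perfectly", {
  set.seed(61)
  co <- data.frame(
    group = factor(rep(c("SIVD", "NC"), each = 20), levels = c("SIVD", "AD", "NC")),
    x = c(rnorm(20, 0, 1), rnorm(20, 10, 1))
  )
  res <- discriminant_classify(co, "x", groups = c("SIVD", "NC"))
  expect_equal(res$rate, 100)
  expect_equal(unname(diag(res$confusion)), c(20, 20))
})

test_that("identically distributed groups classify near chance", {
  set.seed(62)
  rates <- replicate(40, {
    co <- data.frame(
      group = factor(rep(c("SIVD", "AD", "NC"), c(140, 160, 100)),
                     levels = c("SIVD", "AD", "NC")),
      x = rnorm(400), y = rnorm(400)
    )
    discriminant_classify(co, c("x", "y"))$rate
  })
  # chance = max group share = 40%
  expect_lt(abs(mean(rates) - 40), 5)
})

test_that("confusion matrix matches a brute-force discriminant-score oracle", {
  # 9 subjects, 3 groups, 2 features, fixed values
  X <- matrix(c(1.0, 2.0,  1.2, 1.8,  0.8, 2.2,
                3.0, 0.5,  3.2, 0.7,  2.8, 0.4,
                1.5, 4.0,  1.7, 4.2,  1.3, 3.8), ncol = 2, byrow = TRUE)
  g <- factor(rep(c("SIVD", "AD", "NC"), each = 3),
              levels = c("SIVD", "AD", "NC"))
  co <- data.frame(group = g, f1 = X[, 1], f2 = X[, 2])
  res <- discriminant_classify(co, c("f1", "f2"))

  # independent brute force: pooled covariance, explicit score evaluation,
  # no standardisation (LDA is affine-invariant in the features)
  lev <- levels(g)
  mus <- lapply(lev, function(l) colMeans(X[g == l, , drop = FALSE]))
  Sw <- matrix(0, 2, 2)
  for (l in lev) {
    Xl <- X[g == l, , drop = FALSE]
    Sw <- Sw + crossprod(sweep(Xl, 2, colMeans(Xl)))
  }
  Sw <- Sw / (nrow(X) - length(lev))
  Sinv <- solve(Sw)
  pred <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    sc <- sapply(seq_along(lev), function(j) {
      m <- mus[[j]]
      X[i, ] %*% Sinv %*% m - 0.5 * t(m) %*% Sinv %*% m + log(3 / 9)
    })
    pred[i] <- lev[which.max(sc)]
  }
  brute_conf <- table(truth = g, predicted = factor(pred, levels = lev))
  expect_equal(unclass(res$confusion), unclass(brute_conf), ignore_attr = TRUE)
})

test_that("classification agrees with the reference LDA on a well-conditioned toy", {
  set.seed(63)
  co <- data.frame(
    group = factor(rep(c("SIVD", "AD", "NC"), each = 30),
                   levels = c("SIVD", "AD", "NC")),
    a = rnorm(90) + rep(c(0, 1.5, 3), each = 30),
    b = rnorm(90) + rep(c(1, 0, 2), each = 30)
  )
  res <- discriminant_classify(co, c("a", "b"))
  ref <- MASS::lda(group ~ a + b, data = co)
  ref_pred <- predict(ref)$class
  expect_equal(as.character(res$predictions), as.character(ref_pred))
})

test_that("classification is invariant to affine feature transforms", {
  co <- small_cohort(seed = 64)
  cols <- feature_columns(co, "MK", "WM")
  r0 <- discriminant_classify(co, cols)
  co2 <- co
  co2[[cols[1]]] <- co2[[cols[1]]] * 1000 + 77
  co2[[cols[2]]] <- co2[[cols[2]]] * 0.01 - 5
  r1 <- discriminant_classify(co2, cols)
  expect_equal(r1$rate, r0$rate)
  expect_equal(r1$predictions, r0$predictions)
})

test_that("a duplicated feature leaves predictions unchanged (pseudo-inverse)", {
  co <- small_cohort(seed = 65)
  cols <- feature_columns(co, "FA", "WM")
  r0 <- discriminant_classify(co, cols)
  co$dup <- co[[cols[1]]]
  r1 <- discriminant_classify(co, c(cols, "dup"))
  expect_equal(r1$predictions, r0$predictions)
})

test_that("leave-one-out runs and does not exceed resubstitution on overfit panels", {
  co <- small_cohort(seed = 66)
  cols <- feature_columns(co, c("MK", "K_radial", "FA"), "WM")
  res <- discriminant_classify(co, cols, loocv = TRUE)
  expect_true(res$loocv_rate <= res$rate)
  expect_true(res$loocv_rate >= 0 && res$loocv_rate <= 100)
})

test_that("degenerate requests fail informatively", {
  co <- small_cohort(seed = 67)
  expect_error(discriminant_classify(co, "EC_R_MK", groups = "SIVD"),
               "two groups")
  expect_error(discriminant_classify(co, "no_such_col"), "unknown feature")
})

test_that("metric sweep ranks signal-bearing metrics above null metrics", {
  # construction: only MK separates the groups; MD is pure noise
  cal <- default_metric_calibration()
  flat <- cal$metric != "MK"
  for (m in unique(cal$metric[flat])) {
    rows <- cal$metric == m
    cal$mean[rows] <- mean(cal$mean[rows])   # identical across groups
  }
  co <- generate_cohort(cohort_spec(metric_calibration = cal, seed = 68))
  sw <- metric_selection_sweep(co, metrics = c("MK", "MD"), blocks = "WMA",
                               max_size = 2)
  mk_only <- sw$rate[sw$metrics == "MK"]
  md_only <- sw$rate[sw$metrics == "MD"]
  expect_gt(mk_only, md_only)
  expect_true(all(sw$rate[grepl("MK", sw$metrics)] >= md_only))
  expect_error(metric_selection_sweep(co, metrics = "XX"), "unknown metric")
})

test_that("nested feature blocks never reduce the resubstitution rate", {
  co <- small_cohort(seed = 69)
  sw <- metric_selection_sweep(co, metrics = c("MK", "K_radial", "FA"),
                               blocks = c("WMA", "WMA+THA"), max_size = 3)
  tri_wma <- sw$rate[sw$block == "WMA" & sw$metrics == "MK+K_radial+FA"]
  tri_both <- sw$rate[sw$block == "WMA+THA" & sw$metrics == "MK+K_radial+FA"]
  expect_gte(tri_both, tri_wma)
  best <- attr(sw, "best")
  expect_equal(best$rate, max(sw$rate))
})
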