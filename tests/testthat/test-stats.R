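test_that("gender contingency test matches a hand-computed chi-square", {
  # printed group counts: 19/23, 16/34, 15/15 (male/female)
  co <- data.frame(
    group = factor(rep(c("SIVD", "AD", "NC"), c(42, 50, 30)),
                   levels = c("SIVD", "AD", "NC")),
    sex = c(rep(c("M", "F"), c(19, 23)), rep(c("M", "F"), c(16, 34)),
            rep(c("M", "F"), c(15, 15))),
    age = 0, education = 0, duration = 0, scheltens = 0, wmh_ml = 0,
    lacunes = 0, his = 0, casi = 0, mmse = 0
  )
  # independent contingency oracle: chi-square from expected counts by hand
  obs <- rbind(M = c(19, 16, 15), F = c(23, 34, 15))
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  chi_hand <- sum((obs - expd)^2 / expd)
  res <- group_compare_demographics(co, "sex")
  expect_equal(res$statistic, chi_hand, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_gt(res$p, 0.05)   # gender does not differ between groups
})

test_that("demographic comparison flags a strongly shifted group and survives constants", {
  set.seed(51)
  co <- data.frame(group = factor(rep(c("SIVD", "AD", "NC"), each = 40),
                                  levels = c("SIVD", "AD", "NC")))
  co$age <- rnorm(120) + ifelse(co$group == "NC", 5, 0)  # 5 SD shift
  co$flat <- 1.0
  res <- group_compare_demographics(co, c("age", "flat"))
  expect_lt(res$p[res$variable == "age"], 1e-10)
  expect_true(grepl("b", res$pairwise[res$variable == "age"]))
  expect_true(is.na(res$statistic[res$variable == "flat"]))  # no crash
})

test_that("one-way group test holds its nominal size under the null", {
  set.seed(52)
  n_rep <- 400
  pvals <- replicate(n_rep, {
    co <- data.frame(group = factor(rep(c("SIVD", "AD", "NC"), c(20, 20, 20)),
                                    levels = c("SIVD", "AD", "NC")),
                     x = rnorm(60))
    group_compare_demographics(co, "x")$p
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.02); expect_lt(rate, 0.09)
})

test_that("covariate-free adjusted comparison reduces exactly to ANOVA + Tukey", {
  co <- small_cohort(seed = 53)
  y <- compartment_average(co, "K_radial", "WM")
  res <- ancova_tukey(co, y, covariates = character(0))
  fit <- stats::aov(y ~ group, data = data.frame(y = y, group = co$group))
  an <- summary(fit)[[1]]
  expect_equal(res$F, an$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, an$`Pr(>F)`[1], tolerance = 1e-10)
  tk <- stats::TukeyHSD(fit)$group
  # match contrasts (TukeyHSD uses level2-level1 orientation)
  expect_equal(res$pairwise$p[res$pairwise$label == "a"],
               tk["AD-SIVD", "p adj"], tolerance = 1e-8)
  expect_equal(res$pairwise$p[res$pairwise$label == "b"],
               tk["NC-SIVD", "p adj"], tolerance = 1e-8)
  expect_equal(res$pairwise$p[res$pairwise$label == "c"],
               tk["NC-AD", "p adj"], tolerance = 1e-8)
})

test_that("covariates unrelated to feature and group barely move the group test", {
  set.seed(54)
  co <- small_cohort(seed = 54)
  y <- compartment_average(co, "MK", "THA")
  co$noise1 <- rnorm(nrow(co)); co$noise2 <- rnorm(nrow(co))
  with_cov <- ancova_tukey(co, y, covariates = c("noise1", "noise2"))
  without <- ancova_tukey(co, y, covariates = character(0))
  expect_equal(log10(with_cov$p), log10(without$p), tolerance = 0.15)
})

test_that("adjustment removes a pure covariate confound", {
  # feature is a linear function of a covariate; groups balanced on it
  set.seed(55)
  n_rep <- 200
  pvals <- replicate(n_rep, {
    g <- factor(rep(c("SIVD", "AD", "NC"), each = 25),
                levels = c("SIVD", "AD", "NC"))
    z <- rnorm(75)
    co <- data.frame(group = g, z = z)
    y <- 2 * z + rnorm(75, 0, 0.5)
    ancova_tukey(co, y, covariates = "z")$p
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.01); expect_lt(rate, 0.10)
})

test_that("fast F path agrees exactly with the lm-based group test", {
  set.seed(56)
  co <- small_cohort(seed = 56)
  y <- compartment_average(co, "MD", "WM")
  res <- ancova_tukey(co, y)
  covs <- as.matrix(co[, default_covariates()])
  p_fast <- dkidisc:::fast_group_f(y, covs, co$group)
  expect_equal(p_fast, res$p, tolerance = 1e-12)
})

test_that("collinear covariates are dropped with a warning, n <= p errors", {
  co <- small_cohort(seed = 57)
  co$age2 <- co$age * 2
  y <- compartment_average(co, "FA", "WM")
  expect_warning(res <- ancova_tukey(co, y, covariates = c("age", "age2")),
                 "collinear")
  expect_true(is.finite(res$F))
  tiny <- co[c(1, 2, 43, 44, 93, 94), ]
  expect_error(ancova_tukey(tiny, y[c(1, 2, 43, 44, 93, 94)]),
               "more parameters")
})

test_that("clinical constraints filter exactly as specified", {
  co <- data.frame(
    group = factor(c("SIVD", "SIVD", "AD", "AD", "NC", "NC"),
                   levels = c("SIVD", "AD", "NC")),
    cdr = c(0.5, 1, 0.5, 2, NA, NA),
    wmh_ml = c(40, 10, 20, 5, 2, 30),
    lacunes = c(20, 3, 9, 8, 0, 1)
  )
  class(co) <- c("cohort_table", "data.frame")
  expect_equal(nrow(apply_constraint(co, "none")), 6)
  cdr <- apply_constraint(co, "cdr")
  expect_equal(rownames(cdr), c("1", "3", "5", "6"))  # NC NA treated as 0
  wmh <- apply_constraint(co, "wmh")
  expect_equal(rownames(wmh), c("2", "4", "5"))
  lac <- apply_constraint(co, "lacune")
  expect_equal(rownames(lac), c("2", "4", "5", "6"))
})

test_that("the low-lesion-burden constraint depletes the vascular group", {
  # construction: SIVD lesion volumes are centred far above 15 ml
  sizes <- sapply(1:20, function(s) {
    co <- generate_cohort(cohort_spec(seed = 2000 + s))
    attr(apply_constraint(co, "wmh"), "group_sizes")
  })
  expect_true(all(sizes["SIVD", ] < sizes["AD", ]))
})

test_that("an emptied group warns but leaves the remaining groups usable", {
  co <- data.frame(
    group = factor(c("SIVD", "AD", "NC"), levels = c("SIVD", "AD", "NC")),
    wmh_ml = c(50, 5, 5), cdr = c(1, 0.5, NA), lacunes = c(1, 1, 1)
  )
  class(co) <- c("cohort_table", "data.frame")
  expect_warning(out <- apply_constraint(co, "wmh"), "emptied")
  expect_equal(nrow(out), 2)
})
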