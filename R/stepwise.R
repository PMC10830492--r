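#' Correlation-screened, collinearity-pruned stepwise regression
#'
#' Three-stage predictor selection for a cognitive or vascular outcome:
#'
#' 1. *Screen*: keep candidate features whose Pearson correlation with the
#'    outcome is significant at `screen_alpha`.
#' 2. *Prune*: iteratively drop the feature with the largest variance
#'    inflation factor while any VIF >= `vif_cut` (computed among the
#'    surviving candidates; ties broken by column order, so the result does
#'    not depend on input ordering of equivalent features).
#' 3. *Select*: forward-backward stepwise ordinary least squares with the
#'    adjustment covariates forced into the model; candidates enter at
#'    p <= `entry_p` and leave at p >= `removal_p`.
#'
#' Reported effects are the standardized coefficient (beta), the
#' unstandardized 95% confidence interval, p-value, and the survivor VIFs
#' (all below the cut by construction).
#'
#' @param table a `cohort_table`.
#' @param outcome outcome column name (e.g. `"casi"` or `"his"`).
#' @param features candidate feature columns.
#' @param covariates forced-in adjustment covariates.
#' @param screen_alpha Pearson screening level.
#' @param vif_cut variance-inflation-factor removal threshold.
#' @param entry_p,removal_p stepwise entry/removal p-values.
#' @return list with `selected` (data.frame: feature, beta, std_beta,
#'   ci_low, ci_high, p, vif), `screened`, `dropped_vif`, and `model`
#'   (the final `lm`). An empty selection is a normal result.
#' @export
correlate_and_stepwise <- function(table, outcome = "casi", features,
                                   covariates = default_covariates(),
                                   screen_alpha = 0.05, vif_cut = 5,
                                   entry_p = 0.05, removal_p = 0.10) {
  dat <- table[, c(outcome, covariates, features), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  y <- dat[[outcome]]

  # stage 1: Pearson screen
  keep <- features[vapply(features, function(f) {
    x <- dat[[f]]
    if (stats::sd(x) == 0) return(FALSE)
    stats::cor.test(x, y)$p.value < screen_alpha
  }, logical(1))]

  # stage 2: iterative VIF pruning, highest first
  dropped <- character(0)
  cand <- keep
  while (length(cand) > 1) {
    v <- vif_values(dat[, cand, drop = FALSE])
    if (max(v) < vif_cut) break
    worst <- cand[which.max(v)]
    dropped <- c(dropped, worst)
    cand <- setdiff(cand, worst)
  }

  # stage 3: forward-backward stepwise with forced covariates
  in_model <- character(0)
  repeat {
    changed <- FALSE
    avail <- setdiff(cand, in_model)
    if (length(avail) > 0) {
      pv <- vapply(avail, function(f)
        term_p(dat, outcome, covariates, c(in_model, f), f), numeric(1))
      if (min(pv) <= entry_p) {
        in_model <- c(in_model, avail[which.min(pv)])
        changed <- TRUE
      }
    }
    if (length(in_model) > 0) {
      pv <- vapply(in_model, function(f)
        term_p(dat, outcome, covariates, in_model, f), numeric(1))
      if (max(pv) >= removal_p) {
        in_model <- setdiff(in_model, in_model[which.max(pv)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  fit <- fit_ols(dat, outcome, covariates, in_model)
  selected <- if (length(in_model) == 0) {
    data.frame(feature = character(0), beta = numeric(0),
               std_beta = numeric(0), ci_low = numeric(0),
               ci_high = numeric(0), p = numeric(0), vif = numeric(0))
  } else {
    sm <- summary(fit)$coefficients
    ci <- stats::confint(fit)
    vifs <- if (length(in_model) > 1)
      vif_values(dat[, in_model, drop = FALSE])
    else setNames(1, in_model)
    do.call(rbind, lapply(in_model, function(f) {
      b <- sm[f, "Estimate"]
      data.frame(feature = f, beta = b,
                 std_beta = b * stats::sd(dat[[f]]) / stats::sd(y),
                 ci_low = ci[f, 1], ci_high = ci[f, 2],
                 p = sm[f, "Pr(>|t|)"], vif = unname(vifs[f]))
    }))
  }
  list(selected = selected, screened = keep, dropped_vif = dropped,
       model = fit)
}

# VIF of each column against the others (1 / (1 - R^2))
vif_values <- function(df) {
  cols <- names(df)
  vapply(cols, function(f) {
    others <- setdiff(cols, f)
    if (length(others) == 0) return(1)
    # a perfect fit (duplicated feature) legitimately yields R^2 = 1 here
    r2 <- suppressWarnings(summary(stats::lm(
      stats::reformulate(others, response = f), data = df))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

fit_ols <- function(dat, outcome, covariates, feats) {
  rhs <- c(covariates, feats)
  form <- if (length(rhs) == 0) stats::reformulate("1", response = outcome)
  else stats::reformulate(rhs, response = outcome)
  stats::lm(form, data = dat)
}

# partial t-test p-value of `term` in the OLS with covariates + feats
term_p <- function(dat, outcome, covariates, feats, term) {
  fit <- fit_ols(dat, outcome, covariates, feats)
  sm <- summary(fit)$coefficients
  if (!term %in% rownames(sm)) return(1)  # aliased (perfectly collinear)
  sm[term, "Pr(>|t|)"]
}
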