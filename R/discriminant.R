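#' Linear discriminant classification of cohort groups
#'
#' Gaussian linear discriminant analysis with a pooled within-group
#' covariance matrix and proportional priors. Features are standardised
#' internally (classification is therefore invariant to affine rescaling of
#' individual features), and the pooled covariance is inverted by
#' Moore-Penrose pseudo-inverse, so duplicated or collinear features degrade
#' gracefully instead of failing. The headline number is the resubstitution
#' correct-classification rate (the fraction of training subjects the fitted
#' rule labels correctly); leave-one-out cross-validation is available as a
#' companion figure.
#'
#' @param table a `cohort_table` (or data.frame with a `group` column).
#' @param features feature column names.
#' @param groups group levels to include (>= 2).
#' @param loocv also compute the leave-one-out rate.
#' @return object of class `discriminant_result`: `rate` (percent),
#'   `confusion` (rows = true group), `predictions`, `n_per_group`,
#'   `features`, and optionally `loocv_rate`.
#' @export
discriminant_classify <- function(table, features,
                                  groups = c("SIVD", "AD", "NC"),
                                  loocv = FALSE) {
  if (length(groups) < 2) stop("at least two groups are required")
  missing_f <- setdiff(features, names(table))
  if (length(missing_f) > 0)
    stop("unknown feature column(s): ", paste(missing_f, collapse = ", "))
  dat <- table[table$group %in% groups, c("group", features), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  g <- factor(as.character(dat$group), levels = groups)
  if (any(table(g) == 0)) stop("empty group among: ", paste(groups, collapse = ", "))
  X <- as.matrix(dat[, features, drop = FALSE])
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  X <- sweep(sweep(X, 2, mu), 2, sdv, "/")

  pred <- lda_predict(X, g, X)
  conf <- table(truth = g, predicted = pred)
  rate <- 100 * mean(pred == g)
  out <- list(rate = rate, confusion = conf, predictions = pred,
              n_per_group = table(g), features = features, groups = groups)
  if (loocv) {
    cvpred <- factor(rep(NA_character_, nrow(X)), levels = groups)
    for (i in seq_len(nrow(X)))
      cvpred[i] <- lda_predict(X[-i, , drop = FALSE], g[-i],
                               X[i, , drop = FALSE])
    out$loocv_rate <- 100 * mean(cvpred == g)
    out$loocv_predictions <- cvpred
  }
  class(out) <- "discriminant_result"
  out
}

# pooled-covariance LDA: train on (X, g), classify rows of Xnew
lda_predict <- function(X, g, Xnew) {
  lev <- levels(droplevels(g))
  n <- nrow(X)
  k <- length(lev)
  means <- do.call(rbind, lapply(lev, function(l)
    colMeans(X[g == l, , drop = FALSE])))
  Sw <- matrix(0, ncol(X), ncol(X))
  for (l in lev) {
    Xl <- X[g == l, , drop = FALSE]
    Xc <- sweep(Xl, 2, colMeans(Xl))
    Sw <- Sw + crossprod(Xc)
  }
  Sw <- Sw / (n - k)
  Sinv <- MASS::ginv(Sw)
  prior <- as.vector(table(g)[lev]) / n
  scores <- vapply(seq_len(k), function(j) {
    m <- means[j, ]
    as.vector(Xnew %*% (Sinv %*% m)) - 0.5 * sum(m * (Sinv %*% m)) +
      log(prior[j])
  }, numeric(nrow(Xnew)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(Xnew))
  factor(lev[max.col(scores, ties.method = "first")], levels = levels(g))
}

#' @export
print.discriminant_result <- function(x, ...) {
  cat("Linear discriminant analysis over", length(x$features), "features:\n")
  cat("  correct classification:", sprintf("%.1f%%", x$rate),
      "(resubstitution)\n")
  if (!is.null(x$loocv_rate))
    cat("  leave-one-out:", sprintf("%.1f%%", x$loocv_rate), "\n")
  print(x$confusion)
  invisible(x)
}

#' Sweep single/double/triple metric combinations through the classifier
#'
#' Evaluates every 1-, 2- and 3-metric subset of `metrics` over the
#' requested feature blocks (white-matter regions, thalamic regions, or
#' both) and hemispheres, ranking combinations by resubstitution
#' correct-classification rate.
#'
#' @param table a `cohort_table`.
#' @param metrics candidate metric names.
#' @param blocks any of `"WMA"`, `"THA"`, `"WMA+THA"`.
#' @param hemisphere `"both"`, `"L"`, or `"R"`.
#' @param max_size largest combination size (default 3).
#' @param loocv also report leave-one-out rates.
#' @return data.frame ranked by rate, with attribute `best` naming the
#'   argmax combination.
#' @export
metric_selection_sweep <- function(table,
                                   metrics = c("MK", "K_radial", "FA", "MD",
                                               "D_radial"),
                                   blocks = c("WMA", "THA", "WMA+THA"),
                                   hemisphere = "both", max_size = 3L,
                                   loocv = FALSE) {
  known <- metric_names()
  bad <- setdiff(metrics, known)
  if (length(bad) > 0)
    stop("unknown metric name(s): ", paste(bad, collapse = ", "))
  hemi <- if (hemisphere == "both") c("L", "R") else hemisphere
  rows <- list()
  for (blk in blocks) {
    comp <- switch(blk, WMA = "WM", THA = "THA", `WMA+THA` = c("WM", "THA"),
                   stop("unknown block: ", blk))
    for (size in seq_len(max_size)) {
      sets <- utils::combn(metrics, size, simplify = FALSE)
      for (st in sets) {
        cols <- feature_columns(table, metrics = st, compartment = comp,
                                hemisphere = hemi)
        res <- discriminant_classify(table, cols, loocv = loocv)
        rows[[length(rows) + 1L]] <- data.frame(
          block = blk, size = size, metrics = paste(st, collapse = "+"),
          n_features = length(cols), rate = res$rate,
          loocv_rate = if (loocv) res$loocv_rate else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$rate), ]
  rownames(out) <- NULL
  attr(out, "best") <- out[1, ]
  out
}
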