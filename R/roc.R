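#' ROC analysis of a two-group contrast via logistic probability scores
#'
#' Fits a binary logistic model of target-group membership on the feature
#' columns, takes the fitted probabilities as subject scores, and computes
#' the area under the ROC curve as the Mann-Whitney concordance of scores
#' between groups (ties counting one half). Scores are oriented so that
#' AUC >= 0.5 toward the target class. The 95% confidence interval uses the
#' Hanley-McNeil distribution-free standard error; a stratified bootstrap
#' interval is available instead.
#'
#' Perfect separation in the logistic fit triggers a ridge-penalised refit
#' (flagged); the AUC remains well-defined from the scores.
#'
#' @param table a `cohort_table`.
#' @param features feature column names.
#' @param contrast two group labels; the first is the target (diseased)
#'   class.
#' @param ci_method `"hanley-mcneil"` (default) or `"bootstrap"`.
#' @param boot_n bootstrap replicates.
#' @param seed seed for the bootstrap.
#' @return object of class `roc_result`: `auc`, `ci` (95%), `se`,
#'   `contrast`, `scores`, `labels`, `separation_flag`.
#' @export
roc_from_logistic <- function(table, features, contrast = c("SIVD", "NC"),
                              ci_method = c("hanley-mcneil", "bootstrap"),
                              boot_n = 2000L, seed = 1L) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(contrast) == 2)
  dat <- table[table$group %in% contrast, c("group", features), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  y <- as.integer(as.character(dat$group) == contrast[1])
  if (length(unique(y)) < 2) stop("both contrast groups must be present")
  X <- as.matrix(dat[, features, drop = FALSE])

  sep_flag <- FALSE
  scores <- withCallingHandlers(
    {
      fit <- stats::glm.fit(cbind(1, X), y, family = stats::binomial())
      fit$fitted.values
    },
    warning = function(w) {
      sep_flag <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (sep_flag || any(!is.finite(scores)))
    scores <- ridge_logistic_scores(X, y, lambda = 1e-2)

  a <- rank_auc(scores, y)
  oriented <- a < 0.5
  if (oriented) { scores <- -scores; a <- 1 - a }
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  se <- hanley_mcneil_se(a, n1, n0)
  ci <- if (ci_method == "hanley-mcneil") {
    pmin(pmax(a + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  } else {
    set.seed(seed)
    bs <- replicate(boot_n, {
      i1 <- sample(which(y == 1), n1, replace = TRUE)
      i0 <- sample(which(y == 0), n0, replace = TRUE)
      ii <- c(i1, i0)
      rank_auc(scores[ii], y[ii])
    })
    unname(stats::quantile(bs, c(0.025, 0.975)))
  }
  structure(
    list(auc = a, ci = ci, se = se, contrast = contrast, features = features,
         scores = scores, labels = y, n = c(target = n1, reference = n0),
         separation_flag = sep_flag, oriented = oriented),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC %s vs %s: AUC = %.3f (95%% CI %.3f-%.3f), n = %d/%d\n",
              x$contrast[1], x$contrast[2], x$auc, x$ci[1], x$ci[2],
              x$n[1], x$n[2]))
  if (x$separation_flag) cat("  (ridge fallback: separated logistic fit)\n")
  invisible(x)
}

# Mann-Whitney AUC from ranks, ties counted one half
rank_auc <- function(scores, y) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

hanley_mcneil_se <- function(a, n1, n0) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
         (n1 * n0))
}

# ridge-penalised logistic regression by iteratively reweighted LS;
# used when the unpenalised fit separates
ridge_logistic_scores <- function(X, y, lambda = 1e-2, max_iter = 100L) {
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  Z <- cbind(1, Xs)
  beta <- rep(0, ncol(Z))
  pen <- diag(c(0, rep(lambda, ncol(Xs))))
  for (it in seq_len(max_iter)) {
    eta <- as.vector(Z %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    beta_new <- solve(crossprod(Z, w * Z) + pen, crossprod(Z, w * z))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  as.vector(1 / (1 + exp(-Z %*% beta)))
}

#' Empirical ROC curve coordinates
#'
#' Sensitivity/1-specificity pairs at every score threshold; the trapezoidal
#' area under this curve equals the rank-based AUC (used as an internal
#' cross-check).
#'
#' @param scores numeric scores, larger = more target-like.
#' @param y 0/1 labels (1 = target).
#' @return data.frame with threshold, sensitivity, specificity.
#' @export
roc_coordinates <- function(scores, y) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  out <- lapply(th, function(t) {
    pos <- scores >= t
    data.frame(threshold = t,
               sensitivity = sum(pos & y == 1) / sum(y == 1),
               specificity = sum(!pos & y == 0) / sum(y == 0))
  })
  do.call(rbind, out)
}

#' Trapezoidal area under an empirical ROC curve
#' @param coords output of [roc_coordinates()].
#' @export
trapezoid_auc <- function(coords) {
  fpr <- 1 - coords$specificity
  tpr <- coords$sensitivity
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}
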