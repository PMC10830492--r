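#' Default per-group regional-metric calibration
#'
#' Group means and SDs of the eight scalar metrics for the averaged
#' white-matter and averaged thalamus compartments, for the SIVD, AD and NC
#' groups. Diffusivities are in 10^-3 mm^2/s; kurtosis metrics and
#' anisotropies are dimensionless. The AD white-matter MK SD is carried as
#' 0.0606: the source summary table prints .606, two orders of magnitude out
#' of line with every neighbouring SD, which we treat as a decimal-point
#' typo; the printed value is preserved in the `printed_sd` column rather
#' than silently normalised.
#'
#' @return data.frame with columns compartment, metric, group, mean, sd,
#'   printed_sd.
#' @export
default_metric_calibration <- function() {
  rows <- list(
    # compartment, metric, SIVD mean/sd, AD mean/sd, NC mean/sd
    c("WM", "MK",       .88, .071,  .99, .0606, 1.05, .083),
    c("WM", "K_axial",  .44, .030,  .45, .025,  .46, .021),
    c("WM", "K_radial", 1.16, .123, 1.33, .098, 1.41, .127),
    c("WM", "KFA",      .35, .063,  .38, .046,  .39, .034),
    c("WM", "MD",       1.20, .110, 1.10, .068, 1.03, .069),
    c("WM", "D_axial",  1.60, .093, 1.52, .066, 1.46, .061),
    c("WM", "D_radial", 1.00, .123, .90, .072,  .82, .075),
    c("WM", "FA",       .31, .039,  .35, .024,  .37, .030),
    c("THA", "MK",       .81, .063,  .89, .074,  .92, .048),
    c("THA", "K_axial",  .45, .044,  .44, .043,  .45, .023),
    c("THA", "K_radial", .97, .087,  1.0, .088,  1.1, .068),
    c("THA", "KFA",      .28, .087,  .32, .069,  .32, .038),
    c("THA", "MD",       1.32, .256, 1.18, .207, .98, .093),
    c("THA", "D_axial",  1.65, .281, 1.53, .233, 1.29, .100),
    c("THA", "D_radial", 1.15, .245, 1.01, .198, .823, .092),
    c("THA", "FA",       .27, .035,  .30, .035,  .30, .024)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      compartment = r[1], metric = r[2],
      group = c("SIVD", "AD", "NC"),
      mean = as.numeric(r[c(3, 5, 7)]),
      sd = as.numeric(r[c(4, 6, 8)])
    )
  }))
  out$printed_sd <- out$sd
  out$printed_sd[out$compartment == "WM" & out$metric == "MK" &
                   out$group == "AD"] <- 0.606
  out
}

#' Default per-group covariate calibration
#'
#' Group-wise mean and SD of the clinical covariates (age, education,
#' symptom duration in years; lesion-rating scale; WMH volume in ml; lacune
#' count; ischemic score; cognition scores), the male fraction, and the
#' Clinical Dementia Rating stage distribution over stages 0.5 / 1 / 2
#' (NC carries CDR 0).
#'
#' @export
default_covariate_calibration <- function() {
  cont <- do.call(rbind, lapply(list(
    c("age",        73.5, 8.71, 77.9, 5.05, 70.5, 6.25),
    c("education",   5.5, 4.47,  4.9, 4.62,  9.4, 4.14),
    c("duration",    1.5, 1.56,  2.5, 2.22,  0.0, 0.00),
    c("scheltens",  24.7, 7.52, 12.0, 6.59,  7.3, 6.68),
    c("wmh_ml",     38.8, 17.85, 15.2, 14.64, 6.3, 9.28),
    c("lacunes",    20.4, 13.75,  8.6, 8.94,  7.7, 8.48),
    c("his",        10.0, 2.46,   1.8, 1.45,  1.9, 1.39),
    c("casi",       63.3, 14.55, 59.1, 18.25, 89.9, 4.58),
    c("mmse",       19.9, 5.03,  19.1, 5.40, 28.5, 1.07)
  ), function(r) data.frame(
    variable = r[1], group = c("SIVD", "AD", "NC"),
    mean = as.numeric(r[c(2, 4, 6)]), sd = as.numeric(r[c(3, 5, 7)])
  )))
  list(
    continuous = cont,
    male_fraction = c(SIVD = 19 / 42, AD = 16 / 50, NC = 15 / 30),
    cdr_stage_counts = list(SIVD = c(`0.5` = 25, `1` = 12, `2` = 5),
                            AD = c(`0.5` = 22, `1` = 24, `2` = 4),
                            NC = c(`0` = 1))
  )
}

#' Specify a synthetic three-group cohort
#'
#' Defines the generative model for a cohort of SIVD / AD / NC subjects:
#' regional metric features drawn per group from a multivariate normal with
#' exchangeable between-feature correlation `rho`, calibrated by
#' compartment-level means/SDs, and clinical covariates drawn per group and
#' truncated to valid ranges.
#'
#' @param n_sivd,n_ad,n_nc group sizes (defaults 42 / 50 / 30).
#' @param metric_calibration data.frame as [default_metric_calibration()].
#' @param covariate_calibration list as [default_covariate_calibration()].
#' @param rho exchangeable correlation among a subject's regional features.
#' @param metrics which metrics get feature columns.
#' @param seed RNG seed.
#' @export
cohort_spec <- function(n_sivd = 42L, n_ad = 50L, n_nc = 30L,
                        metric_calibration = default_metric_calibration(),
                        covariate_calibration = default_covariate_calibration(),
                        rho = 0.3, metrics = metric_names(), seed = 1L) {
  stopifnot(n_sivd > 0, n_ad > 0, n_nc > 0)
  if (any(metric_calibration$sd < 0)) stop("feature SDs must be >= 0")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  structure(
    list(n = c(SIVD = as.integer(n_sivd), AD = as.integer(n_ad),
               NC = as.integer(n_nc)),
         metric_calibration = metric_calibration,
         covariate_calibration = covariate_calibration,
         rho = rho, metrics = metrics, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort table
#'
#' Draws one subject row per participant: group label, clinical covariates,
#' and one feature column per (region, hemisphere, metric) combination of the
#' default 16-tract white-matter and 14-nucleus thalamic region sets. All
#' regions of a compartment share that compartment's calibrated group
#' mean/SD; within a subject, features are equicorrelated at `rho`
#' (implemented by a shared latent factor, exact for exchangeable
#' correlation). Covariates are truncated to valid ranges (non-negative
#' counts, durations and volumes; cognition scores clipped to their scale
#' ranges) and lacune counts are rounded to integers.
#'
#' @param spec a `cohort_spec`.
#' @return a `data.frame` of class `cohort_table`; feature columns are named
#'   `<region>_<hemisphere>_<metric>`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  set.seed(spec$seed)
  groups <- rep(names(spec$n), spec$n)
  n_tot <- length(groups)
  regions <- rbind(wm_region_names(), thalamic_region_names())
  feat_def <- do.call(rbind, lapply(spec$metrics, function(m)
    data.frame(region = regions$abbrev, hemisphere = regions$hemisphere,
               compartment = regions$compartment, metric = m)))
  feat_def$column <- paste(feat_def$region, feat_def$hemisphere,
                           feat_def$metric, sep = "_")
  p <- nrow(feat_def)
  rho <- spec$rho
  if (rho < 0 && rho < -1 / (p - 1)) {
    warning("rho implies a non-positive-definite covariance; raised to ",
            signif(-1 / (p - 1), 3))
    rho <- -1 / (p - 1)
  }

  cal <- spec$metric_calibration
  feat <- matrix(NA_real_, n_tot, p, dimnames = list(NULL, feat_def$column))
  for (g in names(spec$n)) {
    rows <- which(groups == g)
    u <- stats::rnorm(length(rows))
    e <- matrix(stats::rnorm(length(rows) * p), length(rows), p)
    z <- sqrt(rho) * u %o% rep(1, p) + sqrt(1 - rho) * e
    mu <- numeric(p); sdv <- numeric(p)
    for (jj in seq_len(p)) {
      hit <- cal$compartment == feat_def$compartment[jj] &
        cal$metric == feat_def$metric[jj] & cal$group == g
      mu[jj] <- cal$mean[hit]; sdv[jj] <- cal$sd[hit]
    }
    feat[rows, ] <- sweep(sweep(z, 2, sdv, "*"), 2, mu, "+")
  }

  cov_cal <- spec$covariate_calibration
  covs <- data.frame(row.names = seq_len(n_tot))
  for (v in unique(cov_cal$continuous$variable)) {
    x <- numeric(n_tot)
    for (g in names(spec$n)) {
      rows <- which(groups == g)
      hit <- cov_cal$continuous$variable == v & cov_cal$continuous$group == g
      x[rows] <- stats::rnorm(length(rows), cov_cal$continuous$mean[hit],
                              cov_cal$continuous$sd[hit])
    }
    x <- switch(v,
                education = , duration = , scheltens = ,
                wmh_ml = , lacunes = pmax(x, 0),
                casi = pmin(pmax(x, 0), 100),
                mmse = pmin(pmax(x, 0), 30),
                his = pmax(x, 0),
                x)
    if (v == "lacunes") x <- round(x)
    covs[[v]] <- x
  }
  sex <- character(n_tot)
  cdr <- numeric(n_tot)
  for (g in names(spec$n)) {
    rows <- which(groups == g)
    sex[rows] <- ifelse(
      stats::runif(length(rows)) < cov_cal$male_fraction[[g]], "M", "F")
    stages <- cov_cal$cdr_stage_counts[[g]]
    cdr[rows] <- as.numeric(sample(names(stages), length(rows), replace = TRUE,
                                   prob = stages))
  }
  cdr[groups == "NC"] <- 0

  out <- cbind(
    data.frame(subject = sprintf("S%03d", seq_len(n_tot)),
               group = factor(groups, levels = c("SIVD", "AD", "NC")),
               sex = sex, cdr = cdr),
    covs,
    as.data.frame(feat)
  )
  class(out) <- c("cohort_table", "data.frame")
  attr(out, "feature_def") <- feat_def
  out
}

#' Names of the feature columns of a cohort table
#'
#' @param table a `cohort_table` (or any data.frame with
#'   `<region>_<hemi>_<metric>` feature columns).
#' @param metrics restrict to these metrics (default all).
#' @param compartment `"WM"`, `"THA"`, or both (default).
#' @param hemisphere `"L"`, `"R"`, or both (default).
#' @return character vector of column names.
#' @export
feature_columns <- function(table, metrics = metric_names(),
                            compartment = c("WM", "THA"),
                            hemisphere = c("L", "R")) {
  def <- attr(table, "feature_def")
  if (is.null(def)) {
    regions <- rbind(wm_region_names(), thalamic_region_names())
    def <- do.call(rbind, lapply(metric_names(), function(m)
      data.frame(region = regions$abbrev, hemisphere = regions$hemisphere,
                 compartment = regions$compartment, metric = m)))
    def$column <- paste(def$region, def$hemisphere, def$metric, sep = "_")
    def <- def[def$column %in% names(table), ]
  }
  def$column[def$metric %in% metrics & def$compartment %in% compartment &
               def$hemisphere %in% hemisphere]
}

#' Compartment-average metric columns of a cohort table
#'
#' Unweighted mean over the compartment's regional feature columns, the
#' table analogue of the averaged-compartment summary measures.
#'
#' @param table a `cohort_table`.
#' @param metric one metric name.
#' @param compartment `"WM"` or `"THA"`.
#' @return numeric vector, one value per subject.
#' @export
compartment_average <- function(table, metric, compartment = "WM") {
  cols <- feature_columns(table, metrics = metric, compartment = compartment)
  if (length(cols) == 0) stop("no feature columns for ", metric, "/", compartment)
  rowMeans(table[, cols, drop = FALSE])
}

#' Write a cohort table as CSV
#' @param table a `cohort_table`.
#' @param path output path.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort_csv()]
#' @param path CSV path.
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  out$group <- factor(out$group, levels = c("SIVD", "AD", "NC"))
  class(out) <- c("cohort_table", "data.frame")
  out
}
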