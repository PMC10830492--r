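#' Threshold a lesion probability map
#'
#' Voxels with probability at or above `threshold` (>= by default; a strict
#' `>` is available) form the lesion mask; lesion volume is the voxel count
#' times the voxel volume.
#'
#' @param prob_map 3-D array of probabilities in [0, 1].
#' @param threshold probability cut-off (default 0.5).
#' @param voxel_mm isotropic voxel size in mm.
#' @param strict use `>` instead of `>=`.
#' @return list with `mask` (logical array) and `volume_ml`.
#' @export
threshold_wmh <- function(prob_map, threshold = 0.5, voxel_mm = 2.5,
                          strict = FALSE) {
  rng <- range(prob_map, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("probability map has values outside [0, 1]")
  mask <- if (strict) prob_map > threshold else prob_map >= threshold
  mask[is.na(mask)] <- FALSE
  volume_ml <- sum(mask) * voxel_mm^3 / 1000
  list(mask = mask, volume_ml = volume_ml)
}

#' Regional metric means with lesion and ventricle exclusion
#'
#' For every atlas region and metric, averages the metric map over voxels in
#' the region that are not in the lesion mask, not in the ventricle mask,
#' and valid in the fit. With `invert_wmh = TRUE` the lesion mask is used as
#' an inclusion filter instead (metrics *within* lesions), the variant used
#' to check whether group differences depend on lesion exclusion.
#'
#' @param metrics named list of 3-D metric arrays (as from [fit_volume()]).
#' @param atlas a `label_atlas`.
#' @param wmh_mask optional logical array of lesion voxels.
#' @param ventricle_mask optional logical array of ventricle voxels.
#' @param valid optional logical array of valid-fit voxels.
#' @param invert_wmh restrict to lesion voxels instead of excluding them.
#' @param subject subject identifier carried into the output.
#' @return a tidy `data.frame` of class `region_table`: subject, label,
#'   region, hemisphere, compartment, metric, mean, n_total,
#'   n_excluded_wmh, n_excluded_ventricle, n_used, valid.
#' @export
regional_means <- function(metrics, atlas, wmh_mask = NULL,
                           ventricle_mask = NULL, valid = NULL,
                           invert_wmh = FALSE, subject = "subj") {
  grid <- dim(atlas$volume)
  for (nm in names(metrics))
    if (!all(dim(metrics[[nm]]) == grid))
      stop("metric map '", nm, "' grid does not match atlas grid")
  chk <- function(m, what) {
    if (is.null(m)) return(array(FALSE, grid))
    if (!all(dim(m) == grid)) stop(what, " grid does not match atlas grid")
    array(as.logical(m), grid)
  }
  wmh <- chk(wmh_mask, "wmh_mask")
  vent <- chk(ventricle_mask, "ventricle_mask")
  val <- if (is.null(valid)) array(TRUE, grid) else chk(valid, "valid")

  rows <- list()
  for (r in seq_len(nrow(atlas$names))) {
    info <- atlas$names[r, ]
    in_label <- atlas$volume == info$label
    n_total <- sum(in_label)
    excl_wmh <- in_label & wmh
    excl_vent <- in_label & vent & !wmh   # bookkeeping: no double counting
    use <- if (invert_wmh) in_label & wmh & !vent & val else
      in_label & !wmh & !vent & val
    n_used <- sum(use)
    for (nm in names(metrics)) {
      mval <- if (n_used > 0) mean(metrics[[nm]][use]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, label = info$label, region = info$abbrev,
        hemisphere = info$hemisphere, compartment = info$compartment,
        metric = nm, mean = mval, n_total = n_total,
        n_excluded_wmh = sum(excl_wmh), n_excluded_ventricle = sum(excl_vent),
        n_used = n_used, valid = n_used > 0
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("region_table", "data.frame")
  out
}

#' Assemble subject-level feature columns from a region table
#'
#' @param table a `region_table` (one or more subjects).
#' @param level `"per-region"` (one column per region x metric, named
#'   `<region>_<hemi>_<metric>`), `"hemisphere-average"` (L/R averaged,
#'   `<region>_<metric>`), or `"compartment-average"` (unweighted mean over a
#'   compartment's valid regions, `<compartment>_<metric>`).
#' @return wide `data.frame`, one row per subject; invalid regions yield
#'   `NA` per-region features and are omitted (with their count recorded in
#'   the `n_regions_used` attribute) from averages. A subject whose regions
#'   are all invalid is an error.
#' @export
aggregate_features <- function(table,
                               level = c("per-region", "hemisphere-average",
                                         "compartment-average")) {
  level <- match.arg(level)
  subjects <- unique(table$subject)
  out <- lapply(subjects, function(s) {
    tb <- table[table$subject == s, ]
    if (!any(tb$valid))
      stop("all regions invalid for subject ", s)
    if (level == "per-region") {
      vals <- tb$mean
      names(vals) <- paste(tb$region, tb$hemisphere, tb$metric, sep = "_")
      as.data.frame(as.list(vals))
    } else if (level == "hemisphere-average") {
      key <- paste(tb$region, tb$metric, sep = "_")
      vals <- tapply(ifelse(tb$valid, tb$mean, NA_real_), key,
                     function(v) mean(v, na.rm = TRUE))
      as.data.frame(as.list(vals))[unique(key)]
    } else {
      key <- paste(tb$compartment, tb$metric, sep = "_")
      vals <- tapply(ifelse(tb$valid, tb$mean, NA_real_), key,
                     function(v) mean(v, na.rm = TRUE))
      as.data.frame(as.list(vals))[unique(key)]
    }
  })
  res <- cbind(data.frame(subject = subjects), do.call(rbind, out))
  used <- tapply(table$valid, table$subject,
                 function(v) sum(v) / length(unique(table$metric)))
  attr(res, "n_regions_used") <- used[as.character(subjects)]
  res
}
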