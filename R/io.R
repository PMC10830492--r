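#' Write a simulated dataset to disk
#'
#' Writes the 4-D DWI, label atlas volume, lesion probability map and
#' ventricle mask as NIfTI-1 (with the phantom voxel size in the header),
#' the gradient table as FSL-dialect bvec/bval text files, and a JSON
#' sidecar of ground-truth per-region metric values.
#'
#' @param sim output of [simulate_dwi()].
#' @param scheme the `gradient_table` used.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of paths written.
#' @export
write_simulation <- function(sim, scheme, dir, prefix = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name) file.path(dir, paste0(prefix, "_", name))
  paths <- c(
    dwi = p("dwi.nii.gz"), labels = p("labels.nii.gz"),
    wmh_prob = p("wmh_prob.nii.gz"), ventricle = p("ventricle.nii.gz"),
    bvec = p("dwi.bvec"), bval = p("dwi.bval"), truth = p("truth.json")
  )
  RNifti::writeNifti(nifti_with_pixdim(sim$dwi, sim$voxel_mm), paths["dwi"])
  RNifti::writeNifti(nifti_with_pixdim(sim$labels * 1.0, sim$voxel_mm),
                     paths["labels"])
  RNifti::writeNifti(nifti_with_pixdim(sim$wmh_prob, sim$voxel_mm),
                     paths["wmh_prob"])
  RNifti::writeNifti(nifti_with_pixdim(sim$ventricle * 1.0, sim$voxel_mm),
                     paths["ventricle"])
  write_bvec_bval(scheme, paths["bvec"], paths["bval"])
  truth_means <- lapply(sim$truth, function(m) mean(m, na.rm = TRUE))
  jsonlite::write_json(
    list(voxel_mm = sim$voxel_mm, grid = dim(sim$labels),
         mean_truth = truth_means),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

nifti_with_pixdim <- function(arr, voxel_mm) {
  pd <- c(rep(voxel_mm, 3), rep(1, length(dim(arr)) - 3))
  RNifti::`pixdim<-`(arr, pd)
}

#' Read a 4-D DWI dataset with its gradient table
#'
#' @param dwi_path NIfTI path of the 4-D volume.
#' @param bvec_path,bval_path FSL-dialect gradient files.
#' @return list with `dwi` (4-D array), `scheme` (`gradient_table`) and
#'   `voxel_mm`.
#' @export
read_dwi_dataset <- function(dwi_path, bvec_path, bval_path) {
  img <- RNifti::readNifti(dwi_path)
  scheme <- read_bvec_bval(bvec_path, bval_path)
  if (dim(img)[4] != n_volumes(scheme))
    stop("DWI volume count does not match bvec/bval")
  list(dwi = array(as.numeric(img), dim(img)), scheme = scheme,
       voxel_mm = RNifti::pixdim(img)[1])
}

#' Write fitted metric maps as one NIfTI per metric
#'
#' Files are named `<subject>_<metric>.nii.gz`; invalid voxels carry NaN in
#' the maps, and a separate 0/1 validity mask is written alongside a
#' diagnostics JSON.
#'
#' @param fitted output of [fit_volume()].
#' @param dir output directory.
#' @param subject subject identifier used in file names.
#' @param voxel_mm voxel size recorded in the headers.
#' @return invisibly, the vector of paths written.
#' @export
write_metric_maps <- function(fitted, dir, subject = "subj", voxel_mm = 2.5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(fitted$metrics)) {
    pth <- file.path(dir, paste0(subject, "_", nm, ".nii.gz"))
    RNifti::writeNifti(nifti_with_pixdim(fitted$metrics[[nm]], voxel_mm), pth)
    paths[nm] <- pth
  }
  vpth <- file.path(dir, paste0(subject, "_valid.nii.gz"))
  RNifti::writeNifti(nifti_with_pixdim(fitted$valid * 1.0, voxel_mm), vpth)
  paths["valid"] <- vpth
  jpth <- file.path(dir, paste0(subject, "_diagnostics.json"))
  jsonlite::write_json(
    list(n_valid = sum(fitted$valid),
         mean_iterations = mean(fitted$diagnostics, na.rm = TRUE)),
    jpth, auto_unbox = TRUE, digits = NA)
  paths["diagnostics"] <- jpth
  invisible(paths)
}

#' Read a 3-D NIfTI volume as a plain array
#' @param path NIfTI path.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim(img))
}
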