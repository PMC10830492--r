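#' The default 16-tract white-matter region set
#'
#' Eight structures per hemisphere: corpus callosum genu and body parts,
#' anterior limb of the internal capsule, anterior / superior corona radiata,
#' external capsule, cingulum (cingulate gyrus part), and superior
#' longitudinal fasciculus.
#'
#' @return data.frame with columns label, abbrev, name, hemisphere,
#'   compartment.
#' @export
wm_region_names <- function() {
  structures <- data.frame(
    abbrev = c("GCC", "BCC", "ALIC", "ACR", "SCR", "EC", "CIN", "SLF"),
    name = c("genu of corpus callosum", "body of corpus callosum",
             "anterior limb of internal capsule", "anterior corona radiata",
             "superior corona radiata", "external capsule",
             "cingulum (cingulate gyrus)", "superior longitudinal fasciculus")
  )
  out <- do.call(rbind, lapply(c("L", "R"), function(h)
    cbind(structures, hemisphere = h)))
  out$label <- seq_len(nrow(out))
  out$compartment <- "WM"
  out[, c("label", "abbrev", "name", "hemisphere", "compartment")]
}

#' The default 14-nucleus thalamic region set
#'
#' Seven nuclei per hemisphere: pulvinar, anterior, mediodorsal,
#' ventral-latero-dorsal, central, ventral-anterior and
#' ventral-latero-ventral.
#'
#' @return data.frame with columns label, abbrev, name, hemisphere,
#'   compartment.
#' @export
thalamic_region_names <- function() {
  nuclei <- data.frame(
    abbrev = c("PUL", "AN", "MEDIO", "VLD", "CEN", "VA", "VLV"),
    name = c("pulvinar", "anterior nuclei", "mediodorsal",
             "ventral-latero-dorsal", "central nuclei", "ventral-anterior",
             "ventral-latero-ventral")
  )
  out <- do.call(rbind, lapply(c("L", "R"), function(h)
    cbind(nuclei, hemisphere = h)))
  out$label <- 100L + seq_len(nrow(out))
  out$compartment <- "THA"
  out[, c("label", "abbrev", "name", "hemisphere", "compartment")]
}

#' Construct a label atlas
#'
#' @param volume 3-D integer array of labels (0 = background).
#' @param names data.frame with columns label, abbrev, name, hemisphere,
#'   compartment covering every non-zero label.
#' @param voxel_mm isotropic voxel size in mm.
#' @return object of class `label_atlas`.
#' @export
label_atlas <- function(volume, names, voxel_mm = 2.5) {
  labs <- sort(unique(as.vector(volume)))
  labs <- labs[labs != 0]
  if (any(labs < 0)) stop("labels must be >= 0 (0 = background)")
  missing <- setdiff(labs, names$label)
  if (length(missing) > 0)
    stop("labels without a name-map entry: ", paste(missing, collapse = ", "))
  structure(list(volume = volume, names = names, voxel_mm = voxel_mm),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat("Label atlas:", nrow(x$names), "regions over",
      paste(dim(x$volume), collapse = "x"), "grid,",
      x$voxel_mm, "mm voxels\n")
  invisible(x)
}

#' Build a synthetic label atlas over a voxel subset
#'
#' Partitions the voxels of `mask` (or the whole grid) into contiguous runs,
#' one per region of the name map, in voxel storage order. A stand-in for a
#' co-registered anatomical atlas, used by the simulation pipeline and tests.
#'
#' @param grid length-3 grid shape.
#' @param names region name map (default: the 16 WM tracts).
#' @param mask optional logical array selecting the voxels to label.
#' @param voxel_mm isotropic voxel size in mm.
#' @return a `label_atlas`.
#' @export
synthetic_label_atlas <- function(grid, names = wm_region_names(),
                                  mask = NULL, voxel_mm = 2.5) {
  vol <- array(0L, grid)
  idx <- if (is.null(mask)) seq_len(prod(grid)) else which(mask)
  k <- nrow(names)
  if (length(idx) < k) stop("not enough voxels for ", k, " regions")
  share <- rep(floor(length(idx) / k), k)
  share[k] <- length(idx) - sum(share[-k])
  vol[idx] <- rep(names$label, share)
  label_atlas(vol, names, voxel_mm)
}
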