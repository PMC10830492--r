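#' Build a two-shell diffusion gradient scheme
#'
#' Constructs the acquisition table for a multi-shell diffusion protocol:
#' `n_b0` unweighted volumes followed by the same direction set repeated on
#' each shell. The default protocol (30 directions, b = 1000 and 2000 s/mm^2,
#' 5 b0) yields 65 volumes.
#'
#' The 22-parameter DKI model (log-S0, 6 diffusion-tensor and 15
#' kurtosis-tensor components) needs at least 22 measurements and well-spread
#' directions to be identifiable; a warning is raised for fewer than 15
#' directions.
#'
#' @param n_directions number of unique gradient directions.
#' @param shells numeric vector of non-zero b-values (s/mm^2), one per shell.
#' @param n_b0 number of unweighted (b = 0) volumes.
#' @param seed seed for the deterministic electrostatic-repulsion layout.
#' @return an object of class `gradient_table` with elements `directions`
#'   (volumes x 3; zero rows for b0), `bvalues` (s/mm^2) and `n_b0`.
#' @examples
#' sch <- build_scheme(30, c(1000, 2000), 5)
#' n_volumes(sch)  # 65
#' @export
build_scheme <- function(n_directions, shells = c(1000, 2000), n_b0 = 5L,
                         seed = 42L) {
  if (length(shells) == 0) stop("at least one non-zero shell is required")
  if (any(shells <= 0)) stop("shell b-values must be positive")
  stopifnot(n_directions >= 1, n_b0 >= 0)
  if (n_directions < 15)
    warning("fewer than 15 directions: the 22-parameter kurtosis model ",
            "may be poorly identified", call. = FALSE)
  dirs <- repulsion_directions(n_directions, seed = seed)
  bvals <- c(rep(0, n_b0), rep(shells, each = n_directions))
  all_dirs <- rbind(
    matrix(0, n_b0, 3),
    do.call(rbind, rep(list(dirs), length(shells)))
  )
  structure(
    list(directions = all_dirs, bvalues = bvals, n_b0 = as.integer(n_b0),
         unique_directions = dirs, shells = sort(unique(shells))),
    class = "gradient_table"
  )
}

#' Number of volumes in a gradient scheme
#' @param scheme a `gradient_table`.
#' @export
n_volumes <- function(scheme) length(scheme$bvalues)

#' @export
print.gradient_table <- function(x, ...) {
  cat("Gradient scheme:", n_volumes(x), "volumes (",
      x$n_b0, "b0 +", nrow(x$unique_directions), "directions x",
      length(x$shells), "shells: b =", paste(x$shells, collapse = ", "),
      "s/mm^2 )\n")
  invisible(x)
}

#' Write a gradient scheme as FSL-dialect bvec/bval files
#'
#' `bvec` is written as three whitespace-separated rows (x, y, z components per
#' volume); `bval` as a single row of b-values.
#'
#' @param scheme a `gradient_table`.
#' @param bvec_path,bval_path output file paths.
#' @export
write_bvec_bval <- function(scheme, bvec_path, bval_path) {
  vec <- t(scheme$directions)
  writeLines(apply(vec, 1, function(r) paste(format(r, digits = 8), collapse = " ")),
             bvec_path)
  writeLines(paste(format(scheme$bvalues, trim = TRUE), collapse = " "), bval_path)
  invisible(c(bvec = bvec_path, bval = bval_path))
}

#' Read an FSL-dialect bvec/bval pair into a gradient scheme
#'
#' @param bvec_path path to a 3 x N whitespace-separated bvec file.
#' @param bval_path path to a 1 x N bval file (s/mm^2).
#' @param b0_tol b-values at or below this are treated as b0.
#' @return a `gradient_table`.
#' @export
read_bvec_bval <- function(bvec_path, bval_path, b0_tol = 10) {
  vec <- as.matrix(utils::read.table(bvec_path))
  if (nrow(vec) != 3) stop("bvec file must have exactly 3 rows")
  bvals <- as.numeric(scan(bval_path, quiet = TRUE))
  if (length(bvals) != ncol(vec)) stop("bvec/bval volume counts differ")
  dirs <- t(vec)
  dimnames(dirs) <- NULL
  is_b0 <- bvals <= b0_tol
  nrm <- sqrt(rowSums(dirs^2))
  if (any(!is_b0 & abs(nrm - 1) > 1e-3))
    dirs[!is_b0, ] <- dirs[!is_b0, , drop = FALSE] / nrm[!is_b0]
  dirs[is_b0, ] <- 0
  shells <- sort(unique(bvals[!is_b0]))
  structure(
    list(directions = dirs, bvalues = bvals, n_b0 = sum(is_b0),
         unique_directions = unique(dirs[!is_b0, , drop = FALSE]),
         shells = shells),
    class = "gradient_table"
  )
}

# rows of the scheme that carry diffusion weighting
weighted_rows <- function(scheme) which(scheme$bvalues > 0)
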