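#' Deterministic electrostatic-repulsion direction set
#'
#' Lays out `n` unit vectors on the sphere by minimising an antipodally
#' symmetric Coulomb energy: each point repels every other point and every
#' other point's antipode, so the set is well spread as a set of diffusion
#' *axes* (n and -n are equivalent for diffusion encoding). The layout is
#' deterministic given `seed`: the initial configuration is drawn from a
#' private RNG stream and refined by fixed-step projected gradient descent.
#'
#' @param n number of directions (>= 1).
#' @param seed integer seed controlling the initial configuration.
#' @param n_iter gradient-descent iterations.
#' @return an `n` x 3 matrix of unit row vectors.
#' @export
repulsion_directions <- function(n, seed = 42L, n_iter = 300L) {
  stopifnot(n >= 1)
  if (n == 1L) return(matrix(c(0, 0, 1), 1, 3))
  rng <- local_rng(seed)
  x <- matrix(rng$norm(3L * n), n, 3)
  x <- x / sqrt(rowSums(x^2))
  # keep representatives in the upper hemisphere for reproducible output
  step <- 0.1
  for (it in seq_len(n_iter)) {
    force <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- sweep(x[-i, , drop = FALSE], 2, x[i, ], "-")   # from other points
      d2 <- sweep(-x[-i, , drop = FALSE], 2, x[i, ], "-")  # from antipodes
      r1 <- pmax(sqrt(rowSums(d1^2)), 1e-6)
      r2 <- pmax(sqrt(rowSums(d2^2)), 1e-6)
      f <- -colSums(d1 / r1^3) - colSums(d2 / r2^3)
      force[i, ] <- f
    }
    # project force onto tangent plane and take a bounded step
    force <- force - x * rowSums(force * x)
    fmag <- sqrt(rowSums(force^2))
    scl <- step / pmax(max(fmag), 1e-12)
    x <- x + force * scl
    x <- x / sqrt(rowSums(x^2))
    if (it %% 50L == 0L) step <- step * 0.7
  }
  flip <- x[, 3] < 0
  x[flip, ] <- -x[flip, , drop = FALSE]
  unname(x)
}

#' Minimum pairwise angle of a direction set
#'
#' Angles are computed between diffusion axes, i.e. modulo sign.
#'
#' @param dirs matrix of unit row vectors.
#' @return smallest pairwise angle in degrees.
#' @export
min_pairwise_angle <- function(dirs) {
  n <- nrow(dirs)
  if (n < 2) return(Inf)
  g <- tcrossprod(dirs)
  ang <- acos(pmin(abs(g[upper.tri(g)]), 1)) * 180 / pi
  min(ang)
}

#' Directions spaced uniformly in the plane perpendicular to an axis
#'
#' @param e1 unit axis vector.
#' @param m number of equally spaced azimuths.
#' @return an `m` x 3 matrix of unit vectors orthogonal to `e1`.
#' @keywords internal
perpendicular_circle <- function(e1, m = 64L) {
  e1 <- e1 / sqrt(sum(e1^2))
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * e1) * e1
  u <- u / sqrt(sum(u^2))
  v <- c(
    e1[2] * u[3] - e1[3] * u[2],
    e1[3] * u[1] - e1[1] * u[3],
    e1[1] * u[2] - e1[2] * u[1]
  )
  th <- 2 * pi * (seq_len(m) - 1) / m
  outer(cos(th), u) + outer(sin(th), v)
}

# Private RNG stream: does not disturb the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  draw <- function(fun, ...) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) set.seed(seed) else
      assign(".Random.seed", env$state, globalenv())
    out <- fun(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, globalenv())
    out
  }
  list(
    norm = function(n) draw(stats::rnorm, n),
    unif = function(n) draw(stats::runif, n)
  )
}
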