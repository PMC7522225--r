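# Square-root transform / Fisher-Rao core.
#
# Under h = sqrt(f) the Fisher-Rao geometry of densities becomes the
# standard L2 geometry of the positive orthant of the unit Hilbert sphere:
# the geodesic distance is the arc length acos(<h1, h2>), and exponential /
# inverse-exponential maps between the sphere and its tangent spaces have
# closed forms.  All integrals are trapezoidal on the shared uniform grid.

#' Square-root transform of a density
#'
#' @param f a [density_function()].
#' @return an object of class `srt_function` with values `sqrt(f)` on the
#'   same grid; a point on the positive orthant of the unit Hilbert sphere.
#' @export
srt <- function(f) {
  stopifnot(inherits(f, "density_function"))
  if (any(f$values < 0)) stop_invalid("density values must be >= 0")
  structure(list(grid = f$grid, values = sqrt(f$values),
                 transform = f$transform),
            class = "srt_function")
}

#' Inverse square-root transform
#'
#' The inverse map is unique: `f = h^2`.  Signed tangent excursions are
#' permitted (squaring makes the result a valid density as long as `h` has
#' unit L2 norm), which is what principal-direction paths rely on.
#'
#' @param h an `srt_function`.
#' @return a [density_function()].
#' @export
inverse_srt <- function(h) {
  stopifnot(inherits(h, "srt_function"))
  density_function(h$values^2, grid = h$grid, transform = h$transform)
}

#' Construct an SRT function directly
#'
#' @param values function values on the uniform unit grid; must have unit
#'   trapezoidal L2 norm within `1e-6`.
#' @param grid the grid.
#' @param transform optional [domain_transform()] carried along.
#' @return an `srt_function`.
#' @export
srt_function <- function(values, grid = unit_grid(length(values)),
                         transform = NULL) {
  if (length(values) != length(grid)) stop_invalid("grid/value length mismatch")
  nrm <- trapz(values^2)
  if (abs(nrm - 1) > 1e-6)
    stop_invalid("SRT must have unit L2 norm (integral of h^2 = ",
                 format(nrm), ")")
  structure(list(grid = grid, values = values, transform = transform),
            class = "srt_function")
}

grid_values <- function(g) {
  if (is.list(g)) g$values else as.numeric(g)
}

check_same_grid <- function(g1, g2) {
  v1 <- grid_values(g1); v2 <- grid_values(g2)
  if (length(v1) != length(v2)) stop_invalid("grid mismatch")
  if (is.list(g1) && is.list(g2) &&
      max(abs(g1$grid - g2$grid)) > 1e-12) stop_invalid("grid mismatch")
  invisible(NULL)
}

#' Trapezoidal L2 inner product on the unit grid
#'
#' @param g1,g2 grid functions (numeric vectors or objects with `values`
#'   on the shared grid).
#' @return approximate integral of `g1 * g2` over \[0, 1\].
#' @export
l2_inner <- function(g1, g2) {
  check_same_grid(g1, g2)
  v1 <- grid_values(g1); v2 <- grid_values(g2)
  trapz(v1 * v2)
}

#' L2 norm of a grid function
#'
#' @param g a grid function.
#' @return `sqrt(l2_inner(g, g))`.
#' @export
l2_norm <- function(g) sqrt(l2_inner(g, g))

#' Geodesic distance between two SRT functions
#'
#' The shortest arc on the unit Hilbert sphere:
#' `theta = acos(<h1, h2>)`, with the inner product clipped to \[-1, 1\] to
#' absorb quadrature round-off.
#'
#' @param h1,h2 `srt_function`s on the same grid, unit norm.
#' @return the arc length in radians, in \[0, pi\].
#' @export
geodesic_distance <- function(h1, h2) {
  check_same_grid(h1, h2)
  for (h in list(h1, h2)) {
    nrm <- trapz(grid_values(h)^2)
    if (abs(nrm - 1) > 1e-4)
      stop_invalid("input is not unit-norm (integral of h^2 = ",
                   format(nrm), ")")
  }
  acos(min(1, max(-1, l2_inner(h1, h2))))
}

#' Tangent vector at a point of the SRT sphere
#'
#' @param base the `srt_function` at which the vector is based.
#' @param values perturbation values on the same grid; must be orthogonal
#'   to the base in the trapezoidal inner product (within `1e-6`).
#' @return an object of class `tangent_vector`.
#' @export
tangent_vector <- function(base, values) {
  stopifnot(inherits(base, "srt_function"))
  if (length(values) != length(base$values))
    stop_invalid("grid mismatch")
  ip <- trapz(base$values * values)
  if (abs(ip) > 1e-6)
    stop_invalid("tangent vector not orthogonal to base (<h, v> = ",
                 format(ip), ")")
  structure(list(base = base, values = as.numeric(values)),
            class = "tangent_vector")
}

tangent_values <- function(v) {
  if (inherits(v, "tangent_vector")) v$values else as.numeric(v)
}

#' Exponential map on the SRT sphere
#'
#' `exp_h(v) = cos(||v||) h + sin(||v||) v / ||v||`; a zero vector returns
#' the base point exactly.  The result is renormalised to unit norm to
#' absorb quadrature round-off.
#'
#' @param h base `srt_function`.
#' @param v a [tangent_vector()] based at `h`, or a numeric vector of
#'   tangent values on the same grid.
#' @return an `srt_function`.
#' @export
exp_map <- function(h, v) {
  stopifnot(inherits(h, "srt_function"))
  if (inherits(v, "tangent_vector")) {
    if (max(abs(v$base$values - h$values)) > 1e-8)
      stop_invalid("tangent vector is based at a different point")
  }
  vv <- tangent_values(v)
  if (length(vv) != length(h$values)) stop_invalid("grid mismatch")
  nv <- sqrt(trapz(vv^2))
  if (nv < 1e-12) return(h)
  out <- cos(nv) * h$values + sin(nv) * vv / nv
  out <- out / sqrt(trapz(out^2))
  structure(list(grid = h$grid, values = out, transform = h$transform),
            class = "srt_function")
}

#' Inverse-exponential (log) map on the SRT sphere
#'
#' `exp^{-1}_{h1}(h2) = theta (h2 - cos(theta) h1) / sin(theta)` with
#' `theta` the geodesic distance.  `theta < 1e-9` is treated as the zero
#' limit; near-antipodal pairs (which cannot arise for nonnegative SRTs)
#' raise an error.
#'
#' @param h1 base `srt_function`.
#' @param h2 target `srt_function` on the same grid.
#' @return a [tangent_vector()] at `h1` with norm `theta`.
#' @export
log_map <- function(h1, h2) {
  check_same_grid(h1, h2)
  theta <- geodesic_distance(h1, h2)
  if (theta > pi - 1e-6)
    stop_invalid("near-antipodal inputs: log map is numerically undefined")
  vals <- if (theta < 1e-9) {
    rep(0, length(h1$values))
  } else {
    theta * (h2$values - cos(theta) * h1$values) / sin(theta)
  }
  structure(list(base = h1, values = vals), class = "tangent_vector")
}

srt_matrix <- function(hs) {
  if (is.matrix(hs)) return(hs)
  stopifnot(is.list(hs), length(hs) >= 1)
  m <- length(hs[[1]]$values)
  H <- vapply(hs, function(h) {
    stopifnot(inherits(h, "srt_function"))
    if (length(h$values) != m) stop_invalid("grid mismatch across sample")
    h$values
  }, numeric(m))
  matrix(H, nrow = m)
}

#' Karcher mean of a sample of SRT functions
#'
#' Gradient iteration on the sphere: from the normalised pointwise average,
#' repeatedly shoot along `step` times the mean of the log-mapped sample
#' until the mean tangent (gradient) norm drops below `tol`.  The Karcher
#' variance reported is the sum of squared geodesic distances from the
#' sample to the mean.
#'
#' @param hs list of `srt_function`s (or an m x n matrix of SRT values).
#' @param tol convergence tolerance on the gradient norm.
#' @param max_iter maximum gradient iterations.
#' @param step step size of the gradient update.
#' @return an object of class `karcher_mean` with fields `mean`
#'   (`srt_function`), `variance`, `iterations`, `final_gradient_norm` and
#'   `converged`.  Non-convergence is reported through `converged = FALSE`,
#'   not an error.
#' @export
karcher_mean <- function(hs, tol = 1e-6, max_iter = 100L, step = 0.5) {
  if (is.list(hs) && length(hs) == 0) stop_invalid("empty sample")
  H <- srt_matrix(hs)
  if (ncol(H) == 0) stop_invalid("empty sample")
  w <- trapz_weights(nrow(H))
  res <- karcher_mean_core(H, w, step, tol, as.integer(max_iter))
  transform <- if (is.list(hs)) hs[[1]]$transform else NULL
  mu <- structure(list(grid = unit_grid(nrow(H)),
                       values = as.numeric(res$mean),
                       transform = transform),
                  class = "srt_function")
  structure(list(mean = mu,
                 variance = karcher_variance(mu, H),
                 iterations = res$iterations,
                 final_gradient_norm = res$gradient_norm,
                 converged = res$converged),
            class = "karcher_mean")
}

#' Karcher variance about a candidate mean
#'
#' @param mean an `srt_function` used as centre.
#' @param hs list of `srt_function`s or an m x n matrix of SRT values.
#' @return sum of squared geodesic distances from `hs` to `mean`.
#' @export
karcher_variance <- function(mean, hs) {
  stopifnot(inherits(mean, "srt_function"))
  H <- srt_matrix(hs)
  if (nrow(H) != length(mean$values)) stop_invalid("grid mismatch")
  w <- trapz_weights(nrow(H))
  ip <- pmin(1, pmax(-1, as.numeric(crossprod(H, w * mean$values))))
  sum(acos(ip)^2)
}
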