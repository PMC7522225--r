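# Tangent-space PCA at the Karcher mean.
#
# The sample is linearised by log-mapping every SRT to the tangent space at
# the mean.  Rows are scaled by the square roots of the quadrature weights,
# so plain Euclidean operations (SVD, dot products, distances) agree with
# the L2 structure of the tangent space.  Principal-component scores then
# serve as ordinary Euclidean predictors.

#' Weighted tangent data matrix at a mean
#'
#' Row i holds `log_map(mean, hs[[i]])` on the grid, multiplied pointwise
#' by the square roots of the trapezoidal weights, so Euclidean dot
#' products of rows equal L2 inner products of the tangent functions (and
#' row norms equal geodesic distances to the mean).
#'
#' @param mean base `srt_function` (typically a Karcher mean).
#' @param hs list of `srt_function`s on the same grid.
#' @return an n x m numeric matrix.
#' @export
tangent_matrix <- function(mean, hs) {
  stopifnot(inherits(mean, "srt_function"), is.list(hs), length(hs) >= 1)
  m <- length(mean$values)
  sw <- sqrt(trapz_weights(m))
  V <- t(vapply(hs, function(h) {
    check_same_grid(mean, h)
    log_map(mean, h)$values * sw
  }, numeric(m)))
  V
}

#' Fit tangent-space PCA
#'
#' Singular value decomposition of the (by default row-centred) weighted
#' tangent matrix.  The number of retained components `r` is the smallest
#' count whose cumulative squared-singular-value fraction reaches
#' `variance_threshold`.  Signs are fixed deterministically: each
#' direction's largest-magnitude coordinate is positive.
#'
#' @param V n x m weighted tangent matrix from [tangent_matrix()].
#' @param variance_threshold cumulative variance fraction to retain
#'   (default 0.9999).
#' @param mean optional base `srt_function`, attached so the model can
#'   project new subjects and generate principal-direction paths.
#' @param center row-centre `V` before the SVD (default `TRUE`); at the
#'   exact Karcher mean the tangent vectors average to approximately, but
#'   on a discrete grid not exactly, zero.
#' @return an object of class `tangent_pca` with fields `base`
#'   (`srt_function` or `NULL`), `center` (length-m centring row),
#'   `directions` (r x m, weighted coordinates, orthonormal rows),
#'   `singular_values` (all), `scores` (n x r), `var_fraction`,
#'   `cum_var_fraction` and `r`.
#' @export
fit_tangent_pca <- function(V, variance_threshold = 0.9999, mean = NULL,
                            center = TRUE) {
  V <- as.matrix(V)
  n <- nrow(V)
  if (n < 2) stop_invalid("need at least 2 subjects for PCA")
  ctr <- if (center) colMeans(V) else rep(0, ncol(V))
  Vc <- sweep(V, 2, ctr)
  sv <- svd(Vc)
  d2 <- sv$d^2
  tot <- sum(d2)
  if (tot < 1e-300) {
    r <- 1L
    frac <- rep(0, length(sv$d))
  } else {
    frac <- d2 / tot
    r <- as.integer(which(cumsum(frac) >= variance_threshold - 1e-12)[1])
    if (is.na(r)) r <- length(sv$d)
  }
  U <- sv$v[, seq_len(r), drop = FALSE]
  scores <- Vc %*% U
  # deterministic sign: largest-magnitude coordinate of each direction > 0
  for (k in seq_len(r)) {
    j <- which.max(abs(U[, k]))
    if (U[j, k] < 0) {
      U[, k] <- -U[, k]
      scores[, k] <- -scores[, k]
    }
  }
  structure(list(base = mean, center = ctr, directions = t(U),
                 singular_values = sv$d, scores = scores,
                 var_fraction = frac, cum_var_fraction = cumsum(frac),
                 r = r, n = n,
                 sqrtw = sqrt(trapz_weights(ncol(V)))),
            class = "tangent_pca")
}

#' Convenience wrapper: Karcher mean plus tangent PCA for a sample
#'
#' @param hs list of `srt_function`s.
#' @param variance_threshold cumulative variance fraction to retain.
#' @param ... passed to [karcher_mean()].
#' @return a `tangent_pca` model with the Karcher mean attached.
#' @export
tangent_pca <- function(hs, variance_threshold = 0.9999, ...) {
  km <- karcher_mean(hs, ...)
  V <- tangent_matrix(km$mean, hs)
  fit_tangent_pca(V, variance_threshold = variance_threshold,
                  mean = km$mean)
}

#' Project a new SRT function onto a fitted tangent-PCA model
#'
#' Log-maps the new subject at the model's base mean, applies the
#' quadrature weighting and training centring, and projects onto the
#' retained directions.  Projecting a training subject reproduces its
#' score row.
#'
#' @param model a `tangent_pca` with a base mean attached.
#' @param h an `srt_function` on the model grid.
#' @return numeric score vector of length `model$r`.
#' @export
project_srt <- function(model, h) {
  stopifnot(inherits(model, "tangent_pca"), inherits(h, "srt_function"))
  if (is.null(model$base)) stop_invalid("model has no base mean attached")
  check_same_grid(model$base, h)
  v <- log_map(model$base, h)$values * model$sqrtw
  drop((v - model$center) %*% t(model$directions))
}

#' Principal-direction density path
#'
#' Walks along one principal direction from the mean, at the requested
#' multiples of that component's score standard deviation
#' (`sigma_c / sqrt(n - 1)`), and maps each point back to a density via the
#' exponential map and the inverse square-root transform.  Multiple 0
#' returns the Karcher-mean density exactly.
#'
#' @param model a `tangent_pca` with a base mean attached.
#' @param component principal direction index, <= `model$r`.
#' @param sd_multiples numeric multiples of the score SD (default -2..2).
#' @return list of [density_function()]s, one per multiple.
#' @export
principal_path <- function(model, component = 1L,
                           sd_multiples = c(-2, -1, 0, 1, 2)) {
  stopifnot(inherits(model, "tangent_pca"))
  if (is.null(model$base)) stop_invalid("model has no base mean attached")
  if (component < 1 || component > model$r)
    stop_invalid("`component` out of range (r = ", model$r, ")")
  sd_c <- model$singular_values[component] / sqrt(model$n - 1)
  dir_fun <- model$directions[component, ] / model$sqrtw
  lapply(sd_multiples, function(k) {
    inverse_srt(exp_map(model$base, k * sd_c * dir_fun))
  })
}
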