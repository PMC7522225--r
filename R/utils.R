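# Shared numerical helpers: the uniform grid on [0, 1] and its trapezoidal
# quadrature weights underpin every inner product in the package.

#' Uniform grid on the unit interval
#'
#' @param m number of grid points (endpoints included).
#' @return numeric vector of `m` equally spaced points from 0 to 1.
#' @export
unit_grid <- function(m) {
  stopifnot(m >= 2)
  seq(0, 1, length.out = m)
}

#' Trapezoidal quadrature weights for the uniform unit grid
#'
#' @param m number of grid points.
#' @return weights `w` such that `sum(w * f)` approximates the integral of
#'   `f` over \[0, 1\].
#' @export
trapz_weights <- function(m) {
  stopifnot(m >= 2)
  dx <- 1 / (m - 1)
  w <- rep(dx, m)
  w[c(1L, m)] <- dx / 2
  w
}

#' Trapezoidal integral over the unit grid
#'
#' @param y function values on the uniform grid.
#' @param w optional precomputed weights.
#' @return approximate integral of `y` over \[0, 1\].
#' @export
trapz <- function(y, w = trapz_weights(length(y))) {
  sum(w * y)
}

# Run an expression under a fixed seed without disturbing the caller's RNG
# state; seed = NULL means "use the ambient RNG stream".
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Small deterministic hash of an R object, used to stamp output files so a
# re-run with the same configuration is recognisable.  Polynomial rolling
# hash over the deparsed object; not cryptographic.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  b <- utf8ToInt(s)
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", h)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}
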