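# Permutation test on the geodesic distance between group mean densities.

#' Permutation test for equality of group mean densities
#'
#' The test statistic is `d0`, the geodesic distance between the Karcher
#' means of the two label groups.  The null distribution is built by
#' randomly permuting the labels and recomputing the group means and their
#' distance.  The conventional p-value is the fraction of permutation
#' distances at least as large as `d0`; the `as_printed` direction instead
#' counts permutations with `d0 > d_sigma` (the complementary quantity, see
#' the methods vignette for why both are provided).
#'
#' @param hs list of `srt_function`s (or an m x n matrix of SRT values).
#' @param y binary labels.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed for the permutation stream.
#' @param direction `"conventional"` (default) or `"as_printed"`.
#' @param k multiplicity count for the Bonferroni-adjusted p-value
#'   (default 1, i.e. no adjustment).
#' @param add_one apply the add-one (Phipson-Smyth) correction
#'   `(count + 1) / (n_perm + 1)`; off by default.
#' @param tol,max_iter,step Karcher mean controls.
#' @return an object of class `perm_test_result` with fields `d0`,
#'   `null_distances`, `p_raw`, `p_adjusted`, `n_permutations`, `seed`,
#'   `direction`.
#' @export
perm_test <- function(hs, y, n_perm = 10000L, seed = NULL,
                      direction = c("conventional", "as_printed"),
                      k = 1L, add_one = FALSE,
                      tol = 1e-6, max_iter = 100L, step = 0.5) {
  direction <- match.arg(direction)
  y <- as_binary(y)
  if (length(unique(y)) < 2) stop_invalid("both classes must be present")
  if (n_perm < 1) stop_invalid("`n_perm` must be >= 1")
  H <- srt_matrix(hs)
  if (ncol(H) != length(y)) stop_invalid("hs/y length mismatch")
  w <- trapz_weights(nrow(H))

  obs <- perm_null_core(H, w, matrix(as.integer(y), ncol = 1),
                        step, tol, as.integer(max_iter))
  d0 <- obs[1]

  labels <- with_seed_if(seed, {
    vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
  })
  storage.mode(labels) <- "integer"
  null_d <- as.numeric(perm_null_core(H, w, labels, step, tol,
                                      as.integer(max_iter)))

  count <- if (direction == "conventional") sum(null_d >= d0) else
    sum(d0 > null_d)
  p_raw <- if (add_one) (count + 1) / (n_perm + 1) else count / n_perm
  structure(list(d0 = d0, null_distances = null_d, p_raw = p_raw,
                 p_adjusted = min(1, k * p_raw),
                 n_permutations = as.integer(n_perm), seed = seed,
                 direction = direction),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("Permutation test on geodesic distance between group means\n"))
  cat(sprintf("  d0 = %.4f rad, %d permutations (%s direction)\n",
              x$d0, x$n_permutations, x$direction))
  cat(sprintf("  p = %.4g (adjusted %.4g)\n", x$p_raw, x$p_adjusted))
  invisible(x)
}

#' Bonferroni adjustment of p-values
#'
#' Multiplies each p-value by the number of comparisons and caps at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param k number of comparisons.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, k) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_invalid("p-values must lie in [0, 1]")
  if (k < 1) stop_invalid("`k` must be >= 1")
  pmin(1, p_values * k)
}
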