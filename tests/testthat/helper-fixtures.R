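# Fixtures built in code: analytic densities on the unit grid, random
# smooth densities, and small synthetic pixel cohorts.

uniform_density <- function(m = 512) density_function(rep(1, m))

linear_density <- function(m = 512) density_function(2 * unit_grid(m))

declining_density <- function(m = 512) density_function(2 * (1 - unit_grid(m)))

# Smooth random density: exponential of a low-order Fourier series,
# renormalised.  Stays strictly positive, so its SRT is interior to the
# positive orthant.
random_density <- function(m = 128, amp = 0.8) {
  x <- unit_grid(m)
  co <- rnorm(4, sd = amp)
  logf <- co[1] * sin(2 * pi * x) + co[2] * cos(2 * pi * x) +
    co[3] * sin(4 * pi * x) + co[4] * cos(4 * pi * x)
  density_function(exp(logf), renormalize = TRUE)
}

random_srt <- function(m = 128, amp = 0.8) srt(random_density(m, amp))

random_srt_sample <- function(n, m = 128, amp = 0.5) {
  lapply(seq_len(n), function(i) random_srt(m, amp))
}

# Random tangent vector at h with given norm, by projecting white noise
# onto the tangent space and rescaling.
random_tangent <- function(h, norm = 0.1) {
  w <- trapz_weights(length(h$values))
  z <- rnorm(length(h$values))
  z <- z - sum(w * z * h$values) * h$values
  z <- z * norm / sqrt(sum(w * z^2))
  tangent_vector(h, z)
}

# Two-group pixel cohort: lists of raw um samples plus labels.
two_group_samples <- function(n0, n1, params0, params1, n_px = 1000,
                              seed = 1) {
  withr::with_seed(seed, {
    samples <- c(
      lapply(seq_len(n0), function(i)
        pixel_sample(generate_pixel_sample(params0, n_px),
                     subject_id = sprintf("A%02d", i))),
      lapply(seq_len(n1), function(i)
        pixel_sample(generate_pixel_sample(params1, n_px),
                     subject_id = sprintf("B%02d", i))))
    list(samples = samples, y = rep(c(0L, 1L), c(n0, n1)))
  })
}

# SRT sample for the same two-group design on a small grid.
two_group_srts <- function(n0, n1, params0, params1, n_px = 1000,
                           grid_size = 128, seed = 1) {
  d <- two_group_samples(n0, n1, params0, params1, n_px, seed)
  tr <- pooled_domain_transform(d$samples)
  hs <- lapply(d$samples, function(s)
    srt(estimate_pdf(s, tr, grid_size = grid_size)))
  list(hs = hs, y = d$y, transform = tr, samples = d$samples)
}

tiny_colorbar <- function() {
  colorbar(c(10, 20, 30),
           rbind(c(255L, 0L, 0L), c(0L, 255L, 0L), c(0L, 0L, 255L)),
           background = c(0L, 0L, 0L))
}

# Exhaustive Mann-Whitney AUC oracle (ties counted 1/2), independent of
# the package implementation.
auc_oracle <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
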