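# Synthetic cohort generator: calibration, determinism, rendering.

test_that("pixel sampler is calibrated to the requested tail mass", {
  p <- group_params(peak_location = 40, peak_scale = 5,
                    tail_mass_above_50 = 0.29)
  x <- generate_pixel_sample(p, 2e5, seed = 1)
  expect_true(all(x > 0))
  expect_lt(abs(mean(x > 50) - 0.29), 0.005)

  # with no tail component all mass comes from the main truncated normal;
  # oracle = its closed-form tail probability at 50 um
  p0 <- group_params(peak_location = 40, peak_scale = 5,
                     tail_mass_above_50 = 0)
  x0 <- generate_pixel_sample(p0, 1e4, seed = 2)
  oracle <- (1 - pnorm(50, 40, 5)) / (1 - pnorm(0, 40, 5))
  se <- sqrt(oracle * (1 - oracle) / 1e4)
  expect_lt(abs(mean(x0 > 50) - oracle), 4 * se)
})

test_that("pixel sampler calibration holds across parameter settings", {
  for (tm in c(0.05, 0.30, 0.60)) {
    p <- group_params(tail_mass_above_50 = tm, peak_scale = 4)
    x <- generate_pixel_sample(p, 1e5, seed = 7)
    se <- sqrt(tm * (1 - tm) / 1e5)
    expect_lt(abs(mean(x > 50) - tm), 3 * se + 1e-3)
  }
})

test_that("generators are pure functions of (params, seed)", {
  p <- group_params()
  expect_identical(generate_pixel_sample(p, 500, seed = 42),
                   generate_pixel_sample(p, 500, seed = 42))
  m1 <- generate_thickness_map(p, c(61, 61), 0.1, seed = 9)
  m2 <- generate_thickness_map(p, c(61, 61), 0.1, seed = 9)
  expect_identical(m1$values, m2$values)
  expect_identical(m1$missing, m2$missing)
  # the ambient RNG stream is left untouched
  withr::with_seed(5, {
    before <- runif(1)
  })
  withr::with_seed(5, {
    invisible(generate_pixel_sample(p, 10, seed = 3))
    expect_identical(runif(1), before)
  })
})

test_that("invalid generator arguments are rejected", {
  p <- group_params()
  expect_error(generate_pixel_sample(p, 0), "positive count")
  expect_error(generate_pixel_sample(p, -3), "positive count")
  expect_error(group_params(peak_scale = 0), "peak_scale")
  expect_error(group_params(tail_mass_above_50 = 1), "tail_mass")
  expect_error(generate_thickness_map(p, c(41, 41), 0.1), "6 mm circle")
})

test_that("thickness maps match the marginal and missing fraction", {
  p <- group_params(tail_mass_above_50 = 0.40, missing_fraction = 0)
  map <- generate_thickness_map(p, c(201, 201), 0.03, seed = 4)
  expect_false(any(map$missing))
  mask <- build_etdrs_mask(dim(map$values), map$center, map$pixel_spacing)
  vals <- map$values[mask$labels > 0]
  expect_true(all(vals > 0))
  expect_lt(abs(mean(vals > 50) - 0.40), 0.02)

  p2 <- group_params(missing_fraction = 0.1)
  map2 <- generate_thickness_map(p2, c(121, 121), 0.05, seed = 5)
  in_grid <- build_etdrs_mask(dim(map2$values), map2$center, 0.05)$labels > 0
  expect_lt(abs(mean(map2$missing[in_grid]) - 0.1), 0.01)
})

test_that("smoothed-field maps keep the mixture marginal", {
  p <- group_params(tail_mass_above_50 = 0.30, missing_fraction = 0)
  map <- generate_thickness_map(p, c(201, 201), 0.03, seed = 6,
                                smooth_sigma = 3)
  mask <- build_etdrs_mask(dim(map$values), map$center, 0.03)
  vals <- map$values[mask$labels > 0]
  # spatially correlated pixels: effective sample size shrinks, so allow a
  # wider band than the independent-pixel case
  expect_lt(abs(mean(vals > 50) - 0.30), 0.05)
  # smoothness: neighbouring pixels correlate strongly
  v <- map$values
  expect_gt(cor(as.vector(v[-1, ]), as.vector(v[-nrow(v), ])), 0.8)
})

test_that("cohort generation respects group sizes and the seed", {
  cfg <- cohort_config(seed = 2, map_shape = c(61L, 61L),
                       pixel_spacing = 0.1, layers = "INL")
  cohort <- generate_cohort(cfg)
  expect_length(cohort, 107)
  groups <- vapply(cohort, `[[`, character(1), "group")
  expect_identical(sum(groups == "controls"), 41L)
  expect_identical(sum(groups == "NoDR"), 28L)
  expect_identical(sum(groups == "NPDR"), 38L)
  expect_true(all(vapply(cohort, `[[`, character(1), "laterality") %in%
                    c("left", "right")))

  cohort2 <- generate_cohort(cfg)
  expect_identical(cohort[[5]]$maps$INL$values, cohort2[[5]]$maps$INL$values)
  expect_identical(vapply(cohort, `[[`, character(1), "laterality"),
                   vapply(cohort2, `[[`, character(1), "laterality"))

  empty <- generate_cohort(cohort_config(
    group_sizes = c(controls = 0L, NoDR = 0L, NPDR = 0L), seed = 1,
    map_shape = c(61L, 61L), pixel_spacing = 0.1, layers = "INL"))
  expect_length(empty, 0)
})

test_that("rendering and decoding round-trip through the colorbar", {
  cb <- tiny_colorbar()
  vals <- matrix(c(10, 20, 30, 24, 14, 26), 2, 3)
  map <- thickness_map(vals, missing = matrix(FALSE, 2, 3),
                       pixel_spacing = 2, center = c(1, 2))
  img <- render_heatmap(map, cb)
  # value 24 is nearest 20 -> green
  expect_identical(img[2, 2, ], c(0L, 255L, 0L))
  dec <- decode_thickness_image(img, cb, pixel_spacing = 2, center = c(1, 2))
  quantized <- matrix(cb$values[
    sapply(vals, function(v) which.min(abs(cb$values - v)))], 2, 3)
  expect_identical(dec$values, quantized)
  expect_false(any(dec$missing))

  # missing pixels render as background and decode back to missing
  map2 <- thickness_map(vals, missing = matrix(c(TRUE, rep(FALSE, 5)), 2, 3),
                        pixel_spacing = 2)
  img2 <- render_heatmap(map2, cb)
  expect_identical(img2[1, 1, ], c(0L, 0L, 0L))
  dec2 <- decode_thickness_image(img2, cb, pixel_spacing = 2)
  expect_identical(dec2$missing, map2$missing)

  # constant map at an exact colorbar value -> single-colour image
  map3 <- thickness_map(matrix(20, 3, 3), missing = matrix(FALSE, 3, 3),
                        pixel_spacing = 3)
  img3 <- render_heatmap(map3, cb)
  expect_true(all(img3[, , 2] == 255L) && all(img3[, , c(1, 3)] == 0L))

  expect_error(render_heatmap(map, structure(list(values = numeric(0)),
                                             class = "colorbar")),
               "empty")
})

test_that("cohort disk round-trip preserves values up to quantization", {
  cfg <- cohort_config(group_sizes = c(controls = 2L, NPDR = 2L),
                       layers = "INL", map_shape = c(61L, 61L),
                       pixel_spacing = 0.1, seed = 8)
  cohort <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  cb <- default_colorbar(range = c(0, 200), n = 200)
  write_cohort(cohort, dir, cb)
  back <- read_cohort(dir)
  expect_length(back, 4)
  expect_identical(back[[1]]$group, "controls")
  orig <- cohort[[1]]$maps$INL
  dec <- back[[1]]$maps$INL
  expect_identical(dec$missing, orig$missing)
  err <- abs(dec$values[!dec$missing] - orig$values[!orig$missing])
  expect_lt(max(err), (200 / 199) / 2 + 1e-9)  # half a colorbar step
  expect_identical(dec$laterality, cohort[[1]]$laterality)
})
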