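# Logistic classification, AUC/DeLong machinery, LOOCV evaluation.

test_that("logistic regression respects symmetry and the prediction formula", {
  # perfectly balanced symmetric design: intercept ~ 0
  X <- matrix(c(-1, -1, 1, 1), 4, 1)
  y <- c(0, 0, 1, 1)
  fit <- fit_logistic(X, y)
  expect_lt(abs(fit$coefficients[1]), 1e-6)
  expect_gt(fit$coefficients[2], 0)
  # p = 1 / (1 + exp(-x'beta)); x'beta = 0 -> 0.5
  expect_equal(unname(predict_prob(fit, matrix(0, 1, 1))), 0.5)
  b <- fit$coefficients
  expect_equal(unname(predict_prob(fit, matrix(0.7, 1, 1))),
               1 / (1 + exp(-(b[1] + b[2] * 0.7))))
  expect_error(fit_logistic(X, c(1, 1, 1, 1)), "both classes")
})

test_that("logistic fit matches glm on well-conditioned data", {
  withr::with_seed(14, {
    X <- matrix(rnorm(200 * 2), 200, 2)
    y <- rbinom(200, 1, plogis(0.5 + X[, 1] - 0.8 * X[, 2]))
  })
  ours <- fit_logistic(X, y, ridge = 0)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(unname(ours$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
})

test_that("null labels give near-zero slopes", {
  withr::with_seed(15, {
    X <- matrix(rnorm(500), 500, 1)
    y <- rbinom(500, 1, 0.5)  # independent of X
  })
  fit <- fit_logistic(X, y)
  expect_lt(abs(fit$coefficients[2]), 0.25)
})

test_that("AUC equals the exhaustive pair-counting oracle on small inputs", {
  expect_equal(delong_auc_ci(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc, 1)
  withr::with_seed(16, {
    for (i in 1:100) {
      n <- sample(4:12, 1)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      p <- round(runif(n), 1)  # rounding induces ties
      expect_equal(delong_auc_ci(p, y)$auc, auc_oracle(p, y))
    }
  })
})

test_that("DeLong interval matches pROC and degenerates sensibly", {
  withr::with_seed(17, {
    y <- rep(c(0, 1), each = 40)
    p <- c(rnorm(40), rnorm(40, 1))
  })
  ours <- delong_auc_ci(p, y, level = 0.983)
  ref <- pROC::ci.auc(pROC::roc(y, p, quiet = TRUE, direction = "<"),
                      conf.level = 0.983, method = "delong")
  expect_equal(ours$ci_low, as.numeric(ref[1]), tolerance = 1e-8)
  expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-8)
  expect_equal(ours$ci_high, as.numeric(ref[3]), tolerance = 1e-8)

  perfect <- delong_auc_ci(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$se, 0)
  expect_equal(c(perfect$ci_low, perfect$ci_high), c(1, 1))
  # all-tied scores collapse to a point interval at 0.5, no exception
  tied <- delong_auc_ci(rep(0.5, 6), c(0, 0, 0, 1, 1, 1))
  expect_equal(tied$auc, 0.5)
  expect_equal(tied$se, 0)
})

test_that("DeLong variance is consistent with a bootstrap oracle", {
  withr::with_seed(18, {
    y <- rep(c(0, 1), each = 60)
    p <- c(rnorm(60), rnorm(60, 0.8))
    se_d <- delong_auc_ci(p, y)$se
    boots <- replicate(2000, {
      i0 <- sample(which(y == 0), replace = TRUE)
      i1 <- sample(which(y == 1), replace = TRUE)
      delong_auc_ci(c(p[i0], p[i1]), c(y[i0], y[i1]))$auc
    })
    expect_lt(abs(se_d - sd(boots)) / sd(boots), 0.15)
  })
})

test_that("bonferroni_level splits the alpha budget", {
  expect_equal(bonferroni_level(0.05, 3), 1 - 0.05 / 3)
  expect_equal(bonferroni_level(0.05, 1), 0.95)
  expect_equal(bonferroni_level(0.10, 2), 0.95)
  expect_error(bonferroni_level(0, 3), "overall_alpha")
  expect_error(bonferroni_level(0.05, 0), "k")
})

test_that("Brier score and sensitivity/specificity hand examples", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 7), c(1, 0, 0, 1, 1, 0, 1)), 0.25)
  expect_equal(brier_score(c(0.8, 0.3), c(1, 0)), 0.065)
  expect_error(brier_score(numeric(0), numeric(0)), "empty")

  expect_equal(unname(sens_spec(c(0.9, 0.1), c(1, 0))), c(1, 1))
  expect_equal(unname(sens_spec(c(0.9, 0.1), c(1, 0), threshold = 0)),
               c(1, 0))
  expect_equal(unname(sens_spec(c(0.6, 0.4, 0.6, 0.4), c(1, 1, 0, 0))),
               c(0.5, 0.5))
})

test_that("five-number summary follows the type-7 quantile rule", {
  f <- summary_feature_baseline(list(c(10, 20, 30, 40)))
  expect_equal(unname(f[1, ]), c(25, 10, 40, 17.5, 32.5))
  fc <- summary_feature_baseline(list(rep(7, 9)))
  expect_equal(unname(fc[1, ]), rep(7, 5))
  expect_error(summary_feature_baseline(
    list(pixel_sample(numeric(0), subject_id = "S9"))), "S9")
  # summary features move under affine rescaling (density features do not)
  f2 <- summary_feature_baseline(list(2 * c(10, 20, 30, 40) + 5))
  expect_false(isTRUE(all.equal(unname(f[1, ]), unname(f2[1, ]))))
})

test_that("LOOCV separates well-separated groups and is deterministic", {
  d <- two_group_samples(10, 10,
                         group_params(tail_mass_above_50 = 0.05),
                         group_params(tail_mass_above_50 = 0.60),
                         n_px = 800, seed = 19)
  cfg <- analysis_config(grid_size = 128L)
  rep1 <- loocv_evaluate(d$y, samples = d$samples, config = cfg,
                         features = "density")
  expect_gt(rep1$auc, 0.9)
  expect_identical(rep1$ci_level, 1 - 0.05 / 3)
  rep2 <- loocv_evaluate(d$y, samples = d$samples, config = cfg,
                         features = "density")
  expect_identical(rep1$p_hat, rep2$p_hat)
  reps <- loocv_evaluate(d$y, samples = d$samples, config = cfg,
                         features = "summary")
  expect_gt(reps$auc, 0.9)
  expect_identical(reps$feature_set, "five-number-summary")
})

test_that("label-permuted cohorts give null-range AUC", {
  d <- two_group_samples(20, 20, group_params(), group_params(),
                         n_px = 600, seed = 20)
  cfg <- analysis_config(grid_size = 128L)
  rep0 <- loocv_evaluate(d$y, samples = d$samples, config = cfg,
                         features = "density")
  expect_gt(rep0$auc, 0.3)
  expect_lt(rep0$auc, 0.7)
})

test_that("LOOCV has no label leakage into the held-out prediction", {
  d <- two_group_samples(5, 5,
                         group_params(tail_mass_above_50 = 0.1),
                         group_params(tail_mass_above_50 = 0.5),
                         n_px = 400, seed = 21)
  cfg <- analysis_config(grid_size = 64L)
  base <- loocv_evaluate(d$y, samples = d$samples, config = cfg,
                         features = "density")
  y_flip <- d$y
  y_flip[1] <- 1L - y_flip[1]
  flipped <- loocv_evaluate(y_flip, samples = d$samples, config = cfg,
                            features = "density")
  expect_equal(flipped$p_hat[1], base$p_hat[1], tolerance = 1e-12)
})

test_that("density-feature LOOCV is invariant to affine rescaling of um", {
  d <- two_group_samples(5, 5,
                         group_params(tail_mass_above_50 = 0.1),
                         group_params(tail_mass_above_50 = 0.5),
                         n_px = 400, seed = 22)
  scaled <- lapply(d$samples, function(s)
    pixel_sample(3 * s$values + 10, subject_id = s$subject_id))
  cfg <- analysis_config(grid_size = 64L)
  r1 <- loocv_evaluate(d$y, samples = d$samples, config = cfg, "density")
  r2 <- loocv_evaluate(d$y, samples = scaled, config = cfg, "density")
  expect_identical(r1$auc, r2$auc)
  expect_equal(r1$p_hat, r2$p_hat, tolerance = 1e-9)
  # the summary baseline is not invariant (features change with the scale)
  f1 <- summary_feature_baseline(d$samples)
  f2 <- summary_feature_baseline(scaled)
  expect_false(isTRUE(all.equal(f1, f2)))
})

test_that("LOOCV rejects degenerate class sizes", {
  d <- two_group_samples(2, 5, group_params(), group_params(), n_px = 100,
                         seed = 23)
  expect_error(loocv_evaluate(d$y, samples = d$samples,
                              config = analysis_config(grid_size = 64L)),
               "3 subjects per class")
})
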