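# Classification of disease groups from density-derived features.
#
# Logistic regression on tangent-PCA scores, evaluated with leave-one-out
# cross-validation: each fold refits the domain transform, densities,
# Karcher mean, PCA and classifier on the training subjects only, so no
# information about the held-out subject leaks into feature construction.
# AUC uncertainty uses the DeLong variance estimator with Wald intervals at
# a Bonferroni-corrected confidence level.

#' Fit a logistic regression model
#'
#' Maximum-likelihood fit by iteratively reweighted least squares, with a
#' small ridge penalty on the slope coefficients (never the intercept) to
#' stabilise quasi-separated small folds.
#'
#' @param X n x r numeric predictor matrix.
#' @param y binary response (0/1, logical, or two-level factor).
#' @param ridge ridge penalty on slopes (default `1e-6`).
#' @param max_iter,tol IRLS iteration controls.
#' @return an object of class `logistic_model` with `coefficients`
#'   (intercept first).
#' @export
fit_logistic <- function(X, y, ridge = 1e-6, max_iter = 100L, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as_binary(y)
  if (nrow(X) != length(y)) stop_invalid("X/y length mismatch")
  if (length(unique(y)) < 2)
    stop_invalid("both classes must be present in `y`")
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(ridge, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    wv <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(Xd, y - mu)) - drop(pen %*% beta)
    hess <- crossprod(Xd, Xd * wv) + pen
    delta <- solve(hess, grad)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  if (any(!is.finite(beta))) stop_invalid("logistic fit diverged")
  structure(list(coefficients = drop(beta)), class = "logistic_model")
}

#' Predicted class-1 probability
#'
#' `p = 1 / (1 + exp(-x' beta))` with an implicit leading intercept.
#'
#' @param model a `logistic_model`.
#' @param X n x r predictor matrix (or a single row as a vector).
#' @return numeric vector of probabilities.
#' @export
predict_prob <- function(model, X) {
  stopifnot(inherits(model, "logistic_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  plogis(drop(cbind(1, as.matrix(X)) %*% model$coefficients))
}

as_binary <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_invalid("`y` must be binary (0/1)")
  y
}

#' AUC with DeLong-variance Wald confidence interval
#'
#' The AUC is the Mann-Whitney statistic (ties counted 1/2).  Its standard
#' error comes from the DeLong structural components: the variance of the
#' per-positive and per-negative placement values.  The Wald interval is
#' clipped to \[0, 1\]; perfectly-ranked scores give a zero-width interval.
#'
#' @param p predicted probabilities (or any scores).
#' @param y binary labels.
#' @param level two-sided confidence level (e.g. 0.983).
#' @return list with `auc`, `se`, `ci_low`, `ci_high`, `level`.
#' @export
delong_auc_ci <- function(p, y, level = 0.95) {
  y <- as_binary(y)
  if (length(p) != length(y)) stop_invalid("p/y length mismatch")
  if (length(unique(y)) < 2) stop_invalid("both classes must be present")
  pos <- p[y == 1]; neg <- p[y == 0]
  m <- length(pos); n <- length(neg)
  psi <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)   # placement of each positive among negatives
  v01 <- colMeans(psi)   # placement of each negative among positives
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = auc, se = se,
       ci_low = max(0, auc - z * se),
       ci_high = min(1, auc + z * se),
       level = level)
}

#' Bonferroni-corrected per-comparison confidence level
#'
#' Splitting an overall type-I budget `alpha` across `k` comparisons gives
#' per-comparison level `1 - alpha / k`; for `alpha = 0.05` and three
#' pairwise comparisons this is the 98.3% level.
#'
#' @param overall_alpha overall significance level, in (0, 1).
#' @param k number of comparisons, >= 1.
#' @return per-comparison confidence level.
#' @export
bonferroni_level <- function(overall_alpha, k) {
  if (overall_alpha <= 0 || overall_alpha >= 1)
    stop_invalid("`overall_alpha` must be in (0, 1)")
  if (k < 1) stop_invalid("`k` must be >= 1")
  1 - overall_alpha / k
}

#' Brier score
#'
#' @param p predicted probabilities.
#' @param y binary outcomes.
#' @return mean of `(p - y)^2`.
#' @export
brier_score <- function(p, y) {
  y <- as_binary(y)
  if (length(p) == 0) stop_invalid("empty input")
  if (length(p) != length(y)) stop_invalid("p/y length mismatch")
  mean((p - y)^2)
}

#' Sensitivity and specificity at a probability threshold
#'
#' Predictions with `p >= threshold` count as positive.
#'
#' @param p predicted probabilities.
#' @param y binary labels.
#' @param threshold decision threshold (default 0.5).
#' @return named vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(p, y, threshold = 0.5) {
  y <- as_binary(y)
  if (length(unique(y)) < 2) stop_invalid("both classes must be present")
  pred <- as.integer(p >= threshold)
  c(sensitivity = sum(pred == 1 & y == 1) / sum(y == 1),
    specificity = sum(pred == 0 & y == 0) / sum(y == 0))
}

#' Five-number-summary feature matrix
#'
#' The summary-statistics baseline: per subject, the mean, minimum,
#' maximum and first and third quartiles of the raw thickness values (um).
#' Unlike the density features these are not invariant to affine rescaling
#' of the thickness axis.
#'
#' @param samples list of [pixel_sample()]s or numeric vectors.
#' @param quantile_type quantile definition passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return n x 5 matrix with columns mean, min, max, q1, q3.
#' @export
summary_feature_baseline <- function(samples, quantile_type = 7) {
  out <- t(vapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    v <- if (inherits(s, "pixel_sample")) s$values else as.numeric(s)
    if (length(v) == 0) {
      id <- if (inherits(s, "pixel_sample")) s$subject_id else i
      stop_invalid("empty pixel sample for subject ", id)
    }
    q <- quantile(v, c(0.25, 0.75), type = quantile_type, names = FALSE)
    c(mean = mean(v), min = min(v), max = max(v), q1 = q[1], q3 = q[2])
  }, numeric(5)))
  rownames(out) <- vapply(samples, function(s) {
    if (inherits(s, "pixel_sample")) as.character(s$subject_id) else ""
  }, character(1))
  out
}

#' Leave-one-out cross-validated classification report
#'
#' For density features, every fold recomputes the pooled domain transform
#' (training subjects only, when raw samples are supplied), the kernel
#' density estimates, the Karcher mean, the tangent PCA at the configured
#' variance threshold and the logistic fit, then scores the held-out
#' subject by projection.  For summary features each fold refits the
#' logistic model on the training five-number summaries.  The assembled
#' held-out probabilities yield the AUC with its DeLong Wald interval at
#' the Bonferroni-corrected level, sensitivity/specificity at the
#' configured threshold, and the Brier score.
#'
#' @param y binary labels (one per subject).
#' @param samples list of [pixel_sample()]s (raw um values); required for
#'   summary features and for per-fold transforms.
#' @param densities list of [density_function()]s; used directly (fixed
#'   transform) when `samples` is absent or `config$pca_scope = "global"`
#'   densities are still refit per fold for the mean/PCA.
#' @param config an [analysis_config()].
#' @param features `"density"` or `"summary"`.
#' @return an object of class `classification_report`.
#' @export
loocv_evaluate <- function(y, samples = NULL, densities = NULL,
                           config = analysis_config(),
                           features = c("density", "summary")) {
  features <- match.arg(features)
  y <- as_binary(y)
  n <- length(y)
  if (min(table(y)) < 3)
    stop_invalid("need at least 3 subjects per class for LOOCV")
  p_hat <- numeric(n)

  if (features == "summary") {
    if (is.null(samples)) stop_invalid("summary features need raw samples")
    feat <- summary_feature_baseline(samples, config$quantile_type)
    for (i in seq_len(n)) {
      ytr <- y[-i]
      if (length(unique(ytr)) < 2)
        stop_invalid("fold ", i, ": training labels are single-class")
      fit <- fit_logistic(feat[-i, , drop = FALSE], ytr,
                          ridge = config$ridge)
      p_hat[i] <- predict_prob(fit, feat[i, ])
    }
  } else {
    per_fold <- identical(config$pca_scope, "per_fold")
    if (is.null(samples) && is.null(densities))
      stop_invalid("density features need `samples` or `densities`")
    if (!per_fold || is.null(samples)) {
      # fixed densities: per-fold mean/PCA/classifier only
      if (is.null(densities)) {
        tr <- pooled_domain_transform(samples)
        densities <- lapply(samples, estimate_pdf, transform = tr,
                            grid_size = config$grid_size,
                            bandwidth = config$bandwidth)
      }
      hs <- lapply(densities, srt)
      for (i in seq_len(n)) {
        ytr <- y[-i]
        if (length(unique(ytr)) < 2)
          stop_invalid("fold ", i, ": training labels are single-class")
        model <- tangent_pca(hs[-i],
                             variance_threshold = config$variance_threshold,
                             tol = config$karcher_tol,
                             max_iter = config$karcher_max_iter,
                             step = config$karcher_step)
        fit <- fit_logistic(model$scores, ytr, ridge = config$ridge)
        p_hat[i] <- predict_prob(fit, project_srt(model, hs[[i]]))
      }
    } else {
      # The training-only pooled transform of fold i equals the all-subject
      # transform unless subject i owns the pooled minimum or maximum, so
      # the kernel density estimates can be cached for all other folds
      # without any information about the held-out subject leaking in.
      kde_all <- function(tr) lapply(samples, estimate_pdf, transform = tr,
                                     grid_size = config$grid_size,
                                     bandwidth = config$bandwidth)
      mins <- vapply(samples, function(s) min(s$values), numeric(1))
      maxs <- vapply(samples, function(s) max(s$values), numeric(1))
      tr_all <- pooled_domain_transform(samples)
      hs_all <- lapply(kde_all(tr_all), srt)
      for (i in seq_len(n)) {
        ytr <- y[-i]
        if (length(unique(ytr)) < 2)
          stop_invalid("fold ", i, ": training labels are single-class")
        if (mins[i] <= min(mins[-i]) || maxs[i] >= max(maxs[-i])) {
          tr_i <- pooled_domain_transform(samples[-i])
          hs_i <- lapply(kde_all(tr_i), srt)
        } else {
          hs_i <- hs_all
        }
        model <- tangent_pca(hs_i[-i],
                             variance_threshold = config$variance_threshold,
                             tol = config$karcher_tol,
                             max_iter = config$karcher_max_iter,
                             step = config$karcher_step)
        fit <- fit_logistic(model$scores, ytr, ridge = config$ridge)
        p_hat[i] <- predict_prob(fit, project_srt(model, hs_i[[i]]))
      }
    }
  }

  level <- bonferroni_level(config$overall_alpha, config$n_comparisons)
  ci <- delong_auc_ci(p_hat, y, level = level)
  ss <- sens_spec(p_hat, y, threshold = config$class_threshold)
  structure(list(p_hat = p_hat, y = y,
                 auc = ci$auc, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 ci_level = level,
                 sensitivity = unname(ss["sensitivity"]),
                 specificity = unname(ss["specificity"]),
                 brier = brier_score(p_hat, y),
                 n_per_group = c(n0 = sum(y == 0), n1 = sum(y == 1)),
                 feature_set = if (features == "density")
                   "density-based" else "five-number-summary"),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("LOOCV classification report (%s features)\n", x$feature_set))
  cat(sprintf("  n = %d + %d, AUC = %.3f, %.1f%% CI (%.3f, %.3f)\n",
              x$n_per_group[1], x$n_per_group[2], x$auc, 100 * x$ci_level,
              x$ci_low, x$ci_high))
  cat(sprintf("  sensitivity %.3f, specificity %.3f, Brier %.3f\n",
              x$sensitivity, x$specificity, x$brier))
  invisible(x)
}
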