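# Desk-scale orchestration: cohort in, per-comparison reports out.

#' Analysis configuration
#'
#' Collects every tunable of the pipeline with the study defaults: three
#' pairwise comparisons, 99.99% tangent-PCA variance rule, 98.3%
#' (Bonferroni-corrected) AUC confidence intervals, 0.5 decision threshold.
#'
#' @param grid_size density grid size.
#' @param bandwidth fixed KDE bandwidth on the unit scale, or `NULL` for
#'   Silverman's rule.
#' @param karcher_tol,karcher_max_iter,karcher_step Karcher mean controls.
#' @param variance_threshold cumulative variance retained by tangent PCA.
#' @param overall_alpha overall type-I budget for the AUC intervals.
#' @param n_comparisons number of pairwise comparisons sharing the budget.
#' @param class_threshold probability threshold for sensitivity and
#'   specificity.
#' @param quantile_type quantile rule for the five-number summary.
#' @param ridge logistic slope ridge stabiliser.
#' @param n_perm permutations for the group-difference test.
#' @param pca_scope `"per_fold"` (refit transform/mean/PCA without the
#'   held-out subject; default) or `"global"`.
#' @param p_direction permutation p-value direction, `"conventional"` or
#'   `"as_printed"`.
#' @param seed master seed for the permutation streams.
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(grid_size = 512L, bandwidth = NULL,
                            karcher_tol = 1e-6, karcher_max_iter = 100L,
                            karcher_step = 0.5,
                            variance_threshold = 0.9999,
                            overall_alpha = 0.05, n_comparisons = 3L,
                            class_threshold = 0.5, quantile_type = 7,
                            ridge = 1e-6, n_perm = 2000L,
                            pca_scope = c("per_fold", "global"),
                            p_direction = c("conventional", "as_printed"),
                            seed = 1L) {
  pca_scope <- match.arg(pca_scope)
  p_direction <- match.arg(p_direction)
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop_invalid("`variance_threshold` must be in (0, 1]")
  if (class_threshold < 0 || class_threshold > 1)
    stop_invalid("`class_threshold` must be in [0, 1]")
  structure(list(grid_size = as.integer(grid_size), bandwidth = bandwidth,
                 karcher_tol = karcher_tol,
                 karcher_max_iter = as.integer(karcher_max_iter),
                 karcher_step = karcher_step,
                 variance_threshold = variance_threshold,
                 overall_alpha = overall_alpha,
                 n_comparisons = as.integer(n_comparisons),
                 class_threshold = class_threshold,
                 quantile_type = quantile_type, ridge = ridge,
                 n_perm = as.integer(n_perm), pca_scope = pca_scope,
                 p_direction = p_direction, seed = as.integer(seed)),
            class = "analysis_config")
}

# Oriented in-ETDRS pixel samples for the subjects of one layer.
cohort_samples <- function(cohort, layer) {
  lapply(cohort, function(subj) {
    map <- subj$maps[[layer]]
    if (is.null(map))
      stop_invalid("subject ", subj$subject_id, " has no map for layer ",
                   layer)
    map <- orient_map(map)
    mask <- build_etdrs_mask(dim(map$values), map$center, map$pixel_spacing)
    extract_pixels(map, mask, subject_id = subj$subject_id, layer = layer)
  })
}

#' Run one pairwise comparison for one layer
#'
#' Executes the full pipeline for the two named groups: pixel extraction
#' inside the ETDRS grid, pooled domain transform, kernel density
#' estimates, SRT embedding, group Karcher means with their tail masses
#' above 50 um, LOOCV classification with density and five-number-summary
#' features, and the permutation test on the geodesic distance between the
#' group mean densities.
#'
#' @param cohort list of subjects (as from [generate_cohort()] or
#'   [read_cohort()]).
#' @param layer layer name.
#' @param comparison character vector of two group labels; the second is
#'   coded as class 1.
#' @param config an [analysis_config()].
#' @param with character subset of `c("density", "summary", "perm")`
#'   selecting which evaluations to run (Karcher means and tail masses are
#'   always computed).
#' @return an object of class `pairwise_result`.
#' @export
run_pairwise <- function(cohort, layer, comparison,
                         config = analysis_config(),
                         with = c("density", "summary", "perm")) {
  stopifnot(length(comparison) == 2)
  sel <- vapply(cohort, function(s) s$group %in% comparison, logical(1))
  sub <- cohort[sel]
  if (length(sub) == 0) stop_invalid("no subjects in the comparison groups")
  y <- as.integer(vapply(sub, `[[`, character(1), "group") == comparison[2])
  if (length(unique(y)) < 2)
    stop_invalid("cohort lacks one of the groups: ",
                 paste(comparison, collapse = " vs "))

  samples <- cohort_samples(sub, layer)
  tr <- pooled_domain_transform(samples)
  dens <- lapply(samples, estimate_pdf, transform = tr,
                 grid_size = config$grid_size, bandwidth = config$bandwidth)
  hs <- lapply(dens, srt)

  km <- list()
  tails <- c()
  for (g in comparison) {
    idx <- which(vapply(sub, `[[`, character(1), "group") == g)
    km[[g]] <- karcher_mean(hs[idx], tol = config$karcher_tol,
                            max_iter = config$karcher_max_iter,
                            step = config$karcher_step)
    tails[g] <- tail_mass(inverse_srt(km[[g]]$mean))
  }

  rep_density <- if ("density" %in% with)
    loocv_evaluate(y, samples = samples, densities = dens, config = config,
                   features = "density") else NULL
  rep_summary <- if ("summary" %in% with)
    loocv_evaluate(y, samples = samples, config = config,
                   features = "summary") else NULL
  perm <- if ("perm" %in% with)
    perm_test(hs, y, n_perm = config$n_perm, seed = config$seed,
              direction = config$p_direction, k = config$n_comparisons,
              tol = config$karcher_tol, max_iter = config$karcher_max_iter,
              step = config$karcher_step) else NULL

  structure(list(comparison = comparison, layer = layer,
                 n = length(y), y = y,
                 transform = tr, karcher_means = km, tail_mass = tails,
                 report_density = rep_density, report_summary = rep_summary,
                 perm = perm, config_hash = config_hash(config)),
            class = "pairwise_result")
}

#' Run all configured comparisons across layers
#'
#' @param cohort list of subjects.
#' @param layers layer names (default: layers of the first subject).
#' @param comparisons list of 2-vectors of group labels; default the three
#'   pairwise comparisons of controls, NoDR and NPDR.
#' @param config an [analysis_config()].
#' @param ... passed to [run_pairwise()].
#' @return list of `pairwise_result`s.
#' @export
run_all_pairwise <- function(cohort, layers = NULL, comparisons = NULL,
                             config = analysis_config(), ...) {
  if (is.null(layers)) layers <- names(cohort[[1]]$maps)
  if (is.null(comparisons))
    comparisons <- list(c("NoDR", "NPDR"), c("controls", "NPDR"),
                        c("controls", "NoDR"))
  out <- list()
  for (cmp in comparisons) {
    for (ly in layers) {
      key <- paste(paste(cmp, collapse = "_vs_"), ly, sep = ".")
      out[[key]] <- run_pairwise(cohort, ly, cmp, config = config, ...)
    }
  }
  out
}

#' Tabulate pairwise results
#'
#' Flattens a list of [run_pairwise()] results into the report table
#' layout: comparison, layer, feature set, AUC with its interval,
#' sensitivity, specificity, Brier score and the adjusted permutation
#' p-value.
#'
#' @param results a `pairwise_result` or list of them.
#' @return a data.frame, one row per comparison/layer/feature set.
#' @export
report_table <- function(results) {
  if (inherits(results, "pairwise_result")) results <- list(results)
  rows <- list()
  for (res in results) {
    for (rep in list(res$report_density, res$report_summary)) {
      if (is.null(rep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste(res$comparison, collapse = " vs "),
        layer = res$layer, feature_set = rep$feature_set,
        auc = rep$auc, ci_low = rep$ci_low, ci_high = rep$ci_high,
        ci_level = rep$ci_level,
        sensitivity = rep$sensitivity, specificity = rep$specificity,
        brier = rep$brier,
        p_adjusted = if (is.null(res$perm)) NA_real_ else
          res$perm$p_adjusted,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
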