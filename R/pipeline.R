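## End-to-end orchestration: simulate (or load) -> preprocess -> factor
## model -> audits -> residualize -> consensus cluster -> characterize ->
## reconstructability check, with seeds and stage summaries collected into
## a single report object.

#' Run the full phenotyping pipeline
#'
#' Executes every stage on a synthetic cohort (or a supplied dataset with
#' covariates) and returns a report bundle: the fitted factor model and its
#' audits, residualized scores, the consensus clustering with its selection
#' table, phenotype profiles, demographic balance, and the supervised
#' reconstructability metrics. Fully deterministic for a fixed
#' configuration.
#'
#' @param config A [cohort_config()] describing the synthetic cohort, or
#'   `NULL` when `dataset`, `age`, `sex` are supplied.
#' @param dataset Optional [multiview_dataset()] (skips simulation).
#' @param age,sex Covariates, required with `dataset`.
#' @param k Number of latent factors; when a vector, [mvfa_select_k()]
#'   chooses among them by total variance explained.
#' @param fit_seeds Seeds for the factor-model fits.
#' @param max_iter,tol Factor-model iteration cap and convergence tolerance.
#' @param k_grid_clusters Candidate cluster numbers for the consensus stage.
#' @param B Bootstrap replicates for the consensus stage.
#' @param consensus_seed Base seed of the bootstrap resamples.
#' @param split_seed Seed of the stratified 70/15/15 split.
#' @param run_validation Run the supervised reconstructability stage.
#' @param out_dir Optional directory; when given, stage artifacts (scores,
#'   labels, metric tables, provenance) are written as CSV/JSON-free plain
#'   text.
#' @param verbose Print stage progress.
#' @return Object of class `"mvpheno_report"`.
#' @export
run_pipeline <- function(config = NULL, dataset = NULL, age = NULL, sex = NULL,
                         k = 8L, fit_seeds = 17L, max_iter = 2500L,
                         tol = 1e-4, k_grid_clusters = 4:9, B = 300L,
                         consensus_seed = 2025L, split_seed = 42L,
                         run_validation = TRUE, out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  truth <- NULL
  if (is.null(dataset)) {
    if (is.null(config)) stop("supply 'config' or 'dataset'", call. = FALSE)
    say("simulating cohort (N = %d)", config$n_participants)
    cohort <- generate_cohort(config)
    dataset <- cohort$dataset
    truth <- cohort$truth
    age <- truth$age; sex <- truth$sex
  }
  if (is.null(age) || is.null(sex))
    stop("'age' and 'sex' are required with a supplied dataset", call. = FALSE)

  say("preprocessing (z-scoring gaussian views)")
  std <- preprocess_views(dataset)

  say("fitting factor model (k = %s)", paste(k, collapse = ","))
  if (length(k) > 1L || length(fit_seeds) > 1L) {
    sel <- mvfa_select_k(std, k_grid = k, seeds = fit_seeds,
                         max_iter = max_iter, tol = tol)
    fit <- sel$best_fit
    k_table <- sel$table
  } else {
    fit <- mvfa(std, k = k, seed = fit_seeds, max_iter = max_iter, tol = tol)
    k_table <- NULL
  }
  ev <- variance_explained(fit)
  audit <- if (fit$k >= 2L) factor_correlation_audit(fit) else NULL

  say("residualizing factor scores on age, age^2, sex")
  rs <- residualize_factors(factor_scores(fit), age, sex)

  say("consensus clustering (B = %d, K grid %s)", B,
      paste(range(k_grid_clusters), collapse = "-"))
  cons <- consensus_cluster(rs$z_res, k_grid = k_grid_clusters, B = B,
                            base_seed = consensus_seed)

  say("characterizing phenotypes")
  profile <- cluster_factor_profiles(rs$z_res, cons$labels)
  balance <- demographic_balance(cons$labels, age, sex)

  features <- do.call(cbind, std$views)
  validation <- NULL
  if (run_validation) {
    say("supervised reconstructability check")
    split <- split_cohort(cons$labels, seed = split_seed)
    cv <- crossval_classifier(features[split$train, , drop = FALSE],
                              cons$labels[split$train], seed = split_seed)
    holdout <- evaluate_holdout(features, cons$labels, split)
    validation <- list(split = split, cv = cv, holdout = holdout)
  }

  ari_truth <- if (!is.null(truth))
    adjusted_rand_index(cons$labels, truth$labels_true) else NA_real_

  report <- structure(list(
    dataset = dataset, truth = truth, fit = fit, ev = ev,
    factor_audit = audit, k_table = k_table, residualized = rs,
    confound_audit = confound_audit(rs), consensus = cons,
    profile = profile, balance = balance, validation = validation,
    ari_vs_truth = ari_truth,
    seeds = list(fit = fit_seeds, consensus = consensus_seed,
                 split = split_seed,
                 cohort = if (!is.null(config)) config$seed else NA)),
    class = "mvpheno_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.mvpheno_report <- function(x, ...) {
  cat("== Multi-view phenotyping report ==\n")
  cat(sprintf("Factor model: K = %d, EV_total = %.3f, %s\n", x$fit$k,
              x$ev$ev_total,
              if (x$fit$converged) "converged" else "iteration cap"))
  if (!is.null(x$factor_audit))
    cat(sprintf("Inter-factor |r| max = %.3f over %d pairs\n",
                x$factor_audit$max_abs, x$factor_audit$n_pairs))
  cat(sprintf("Confound audit: max |Spearman rho age| = %.4f, max |Cohen's d sex| = %.4f\n",
              x$confound_audit$max_abs_spearman_age,
              x$confound_audit$max_abs_cohens_d_sex))
  cat(sprintf("Consensus: selected K = %d, sizes %s\n", x$consensus$selected_k,
              paste(table(x$consensus$labels), collapse = ", ")))
  if (!is.na(x$ari_vs_truth))
    cat(sprintf("ARI vs planted labels: %.3f\n", x$ari_vs_truth))
  if (!is.null(x$validation))
    cat(sprintf("Reconstructability: CV macro-F1 %.3f +/- %.3f, CV AUC %.3f +/- %.3f; holdout macro-F1 %.3f, AUC %.3f\n",
                x$validation$cv$macro_f1_mean, x$validation$cv$macro_f1_sd,
                x$validation$cv$auc_mean, x$validation$cv$auc_sd,
                x$validation$holdout$macro_f1, x$validation$holdout$ovr_auc))
  invisible(x)
}

#' Write pipeline artifacts as plain-text files
#'
#' Residual scores, final labels, the K-selection table, phenotype profiles,
#' and a provenance file recording every seed.
#'
#' @param report An `"mvpheno_report"` from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- report$dataset$participant_ids
  utils::write.csv(data.frame(participant_id = ids, report$residualized$z_res),
                   file.path(out_dir, "residual_scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(participant_id = ids,
                              phenotype = report$consensus$labels),
                   file.path(out_dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(report$consensus$metrics,
                   file.path(out_dir, "k_selection.csv"), row.names = FALSE)
  utils::write.csv(data.frame(cluster = report$profile$cluster,
                              size = report$profile$sizes,
                              centroid_distance = report$profile$centroid_distance,
                              report$profile$means, check.names = FALSE),
                   file.path(out_dir, "phenotype_profiles.csv"),
                   row.names = FALSE)
  seeds <- report$seeds
  writeLines(c("stage,seed",
               sprintf("cohort,%s", seeds$cohort),
               sprintf("fit,%s", paste(seeds$fit, collapse = ";")),
               sprintf("consensus,%s", seeds$consensus),
               sprintf("split,%s", seeds$split)),
             file.path(out_dir, "provenance.csv"))
  invisible(out_dir)
}

#' Two-dimensional embedding of the residualized factor space
#'
#' Plain 2-component PCA of the residual scores, intended for cluster
#' visualization in reports.
#'
#' @param z_res N x K residual score matrix.
#' @return N x 2 matrix of principal-component coordinates.
#' @export
embed_2d <- function(z_res) {
  p <- stats::prcomp(as.matrix(z_res), rank. = 2L)
  p$x[, 1:2, drop = FALSE]
}
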