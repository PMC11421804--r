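#' End-to-end CAP state-trait analysis
#'
#' Runs the full analysis on a cohort: split-half permutation CAP discovery,
#' basis-CAP construction over the dominant solution size(s), relabeling and
#' permutation-averaging of temporal metrics, reliability and three-axes
#' state-trait statistics, neural feature matrix + subgroups + neural PCA,
#' behavioral preparation + PCA permutation test, delta-occurrence
#' statistics, and the neuro-behavioral association with split-half
#' cross-validation. Fully reproducible from `seed`.
#'
#' @param cohort A preprocessed [cap_cohort()].
#' @param behavior Behavioral tibble (`subject_id` + variables), raw.
#' @param behavior_meta Metadata tibble (`variable`, `is_rt`, ...), optional.
#' @param n_perm Number of split-half permutations.
#' @param k_range k-scan range (default 2:15).
#' @param seed Master seed.
#' @param fd_threshold Scrubbing threshold, mm.
#' @param cut_frac Dendrogram cut fraction for subgroups (default 0.70).
#' @param n_behavior_perm Permutations for the behavioral PCA test.
#' @param n_neural Neural components in the association model (default 3).
#' @param k_pair Competing solution sizes for delta occurrence
#'   (default: the two most frequent k-hats).
#' @param reference_patterns Optional K x P matrix with rownames; when given,
#'   basis CAPs are renamed by matching to it (synthetic ground truth).
#' @param silhouette_subsample Passed to [scan_k()].
#'
#' @return A `cap_pipeline_result` list; see the elements' own help pages.
#' @export
run_cap_pipeline <- function(cohort, behavior = NULL, behavior_meta = NULL,
                             n_perm = 100L, k_range = 2:15, seed = 1L,
                             fd_threshold = 0.5, cut_frac = 0.70,
                             n_behavior_perm = 1000L, n_neural = 3L,
                             k_pair = NULL, reference_patterns = NULL,
                             silhouette_subsample = 2000L) {
  seeds <- derive_seeds(seed, 4L)
  ledger <- run_permutations(cohort, n_perm, k_range, base_seed = seeds[1],
                             fd_threshold = fd_threshold,
                             silhouette_subsample = silhouette_subsample)
  occ <- k_occurrence(ledger)
  k_levels <- occ$k_hat[order(occ$n, decreasing = TRUE)]
  k_main <- max(head(k_levels[occ$n[order(occ$n, decreasing = TRUE)] >= 2], 2))

  basis <- build_basis_set(ledger, k_main)
  if (!is.null(reference_patterns)) {
    basis <- label_basis_set(basis, reference_patterns)
  }
  cross_split <- tryCatch(basis_cross_split_similarity(ledger, k_main),
                          error = function(e) NULL)

  per_perm <- relabel_ledger_metrics(ledger, basis)
  agg_zero <- aggregate_metrics(per_perm, basis$labels, absent_as_zero = TRUE)
  agg_present <- aggregate_metrics(per_perm, basis$labels, absent_as_zero = FALSE)

  reliability <- day_reliability(agg_present)
  three_axes <- three_axes_table(agg_zero)

  features <- build_feature_matrix(agg_zero, cap_labels = basis$labels)
  subgroups <- cluster_subgroups(features, cut_frac = cut_frac)
  npca <- neural_pca(features, n_components = n_neural)

  delta <- if (is.null(k_pair)) {
    ks <- sort(occ$k_hat[order(occ$n, decreasing = TRUE)][1:min(2, nrow(occ))])
    if (length(ks) == 2L) occurrence_stats(ledger, ks) else NULL
  } else {
    occurrence_stats(ledger, k_pair)
  }

  beh_out <- NULL
  if (!is.null(behavior)) {
    prepared <- prepare_behavior(behavior, behavior_meta)
    pca_test <- pca_permutation_test(prepared, n_perm = n_behavior_perm,
                                     seed = seeds[2])
    bscores <- tibble::tibble(
      subject_id = prepared$subject_id,
      bpc1 = fix_pca_signs(pca_test$pca)$x[, 1]
    )
    model_df <- dplyr::inner_join(bscores, npca$scores, by = "subject_id") |>
      dplyr::inner_join(cohort$subjects, by = "subject_id")
    assoc <- fit_association(
      model_df, response = "bpc1",
      predictors = paste0("PC", seq_len(n_neural)),
      covariates = intersect(c("age", "sex"), names(model_df))
    )
    cv <- tryCatch(
      crossval_predict(features, prepared, cohort$subjects,
                       n_perm = min(100L, n_perm), n_neural = n_neural,
                       seed = seeds[3]),
      error = function(e) NULL
    )
    tt <- tryCatch(subgroup_ttests(bscores, subgroups$assignments),
                   error = function(e) NULL)
    beh_out <- list(prepared = prepared, pca_test = pca_test,
                    association = assoc, crossval = cv, subgroup_tests = tt)
  }

  structure(list(
    ledger = ledger, k_occurrence = occ, k_main = k_main,
    basis = basis, basis_cross_split = cross_split,
    per_perm_metrics = per_perm,
    metrics = agg_zero, metrics_present_only = agg_present,
    reliability = reliability, three_axes = three_axes,
    features = features, subgroups = subgroups, neural_pca = npca,
    delta_occurrence = delta,
    behavior = beh_out,
    seed = seed
  ), class = "cap_pipeline_result")
}

#' @export
print.cap_pipeline_result <- function(x, ...) {
  cat("<cap_pipeline_result>\n")
  cat(sprintf("  k occurrence: %s\n",
              paste(sprintf("k=%d %.0f%%", x$k_occurrence$k_hat,
                            100 * x$k_occurrence$rate), collapse = ", ")))
  cat(sprintf("  basis: k = %d (%s)\n", x$basis$k,
              paste(x$basis$labels, collapse = ", ")))
  cat(sprintf("  subgroups: %s subjects\n",
              paste(x$subgroups$sizes, collapse = "/")))
  if (!is.null(x$behavior)) {
    cat(sprintf("  behavioral PC1 variance: %.1f%%; association R2 = %.3f\n",
                x$behavior$pca_test$results$var_explained[1],
                x$behavior$association$model_fit$r_squared))
  }
  invisible(x)
}
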