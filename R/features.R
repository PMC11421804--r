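#' Build the per-subject neural state-trait feature matrix
#'
#' Arranges the permutation-averaged temporal metrics into one row per
#' subject with a fixed column schema: (metric in fo, mean_dt, var_dt) x
#' (CAP label) x (day), named `{metric}_{cap}_d{day}` — 3 x 5 x 2 = 30
#' columns for the canonical five-CAP label set. CAPs absent for a subject
#' contribute zeros (use `absent_as_zero = TRUE` aggregates).
#'
#' @param agg Aggregated metrics from [aggregate_metrics()].
#' @param cap_labels Ordered CAP label set (default: the states present).
#' @param metrics Metric columns (default `fo`, `mean_dt`, `var_dt`).
#'
#' @return Tibble: `subject_id` plus one column per schema cell, with a
#'   `schema` attribute (tibble of `column`, `metric`, `state`, `day`).
#' @export
build_feature_matrix <- function(agg, cap_labels = NULL,
                                 metrics = c("fo", "mean_dt", "var_dt")) {
  cap_labels <- cap_labels %||% sort(unique(agg$state))
  days <- sort(unique(agg$day))
  missing_day <- dplyr::group_by(agg, .data$subject_id) |>
    dplyr::summarise(n_days = dplyr::n_distinct(.data$day)) |>
    dplyr::filter(.data$n_days < length(days))
  if (nrow(missing_day) > 0L) {
    abort(sprintf("subjects missing a day: %s",
                  paste(missing_day$subject_id, collapse = ", ")))
  }
  schema <- tidyr::expand_grid(metric = metrics, state = cap_labels, day = days)
  schema$column <- sprintf("%s_%s_d%d", schema$metric, schema$state, schema$day)

  long <- tidyr::pivot_longer(agg, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  long <- dplyr::filter(long, .data$state %in% cap_labels)
  long$column <- sprintf("%s_%s_d%d", long$metric, long$state, long$day)
  wide <- tidyr::pivot_wider(long, id_cols = "subject_id",
                             names_from = "column", values_from = "value",
                             values_fill = 0)
  for (col in schema$column) if (!col %in% names(wide)) wide[[col]] <- 0
  out <- dplyr::select(wide, "subject_id", dplyr::all_of(schema$column))
  attr(out, "schema") <- schema
  out
}

feature_values <- function(features) {
  x <- as.matrix(features[setdiff(names(features), "subject_id")])
  rownames(x) <- features$subject_id
  x
}

#' Subject subgroups by hierarchical clustering of neural features
#'
#' Ward-linkage (Euclidean) agglomerative clustering of the feature matrix;
#' flat subgroups are read off by cutting the dendrogram at
#' `cut_frac x (height of the final merge)` (default 0.70). Columns are
#' z-scored first by default (FO is a fraction, DT is in TRs). Subgroup ids
#' are ordered by descending size.
#'
#' @param features Feature tibble from [build_feature_matrix()].
#' @param cut_frac Dendrogram cut as a fraction of the final merge height.
#' @param standardize Z-score columns before clustering (default `TRUE`).
#'
#' @return A `cap_subgroups`: list with `assignments` (tibble `subject_id`,
#'   `subgroup`), `tree` (hclust), `cut_height`, `sizes`.
#' @export
cluster_subgroups <- function(features, cut_frac = 0.70, standardize = TRUE) {
  x <- feature_values(features)
  if (nrow(x) < 3L) abort("need >= 3 subjects")
  if (standardize) {
    keep <- apply(x, 2L, sd) > 0
    x <- scale(x[, keep, drop = FALSE])
  }
  d <- dist(x)
  if (ncol(x) == 0L || max(d) == 0) {
    warn("all subjects have identical features; returning a single cluster")
    return(structure(list(
      assignments = tibble::tibble(subject_id = rownames(feature_values(features)),
                                   subgroup = 1L),
      tree = NULL, cut_height = 0, sizes = nrow(feature_values(features))
    ), class = "cap_subgroups"))
  }
  hc <- hclust(d, method = "ward.D2")
  h_cut <- cut_frac * max(hc$height)
  cl <- cutree(hc, h = h_cut)
  if (length(unique(cl)) == 1L) {
    warn("all subjects fall in a single cluster at this cut height")
  }
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  cl <- relabel[as.character(cl)]
  structure(list(
    assignments = tibble::tibble(subject_id = rownames(x),
                                 subgroup = as.integer(cl)),
    tree = hc, cut_height = h_cut,
    sizes = as.integer(sizes)
  ), class = "cap_subgroups")
}

#' @export
print.cap_subgroups <- function(x, ...) {
  cat(sprintf("<cap_subgroups> %d subgroups of sizes %s (cut at %.3g)\n",
              length(x$sizes), paste(x$sizes, collapse = "/"), x$cut_height))
  invisible(x)
}

#' PCA of the neural state-trait feature space
#'
#' PCA of the (by default z-scored) subject-by-feature matrix with a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive). For each component the 30 loadings are split into
#' the two 15-vectors belonging to day 1 and day 2 and their Pearson
#' correlation reported: near +1 marks a day-consistent component, a
#' strongly negative value marks a day-flip component carrying day-to-day
#' (state) variance.
#'
#' @param features Feature tibble from [build_feature_matrix()].
#' @param n_components Components to report (default 3).
#' @param standardize Z-score columns first (default `TRUE`).
#'
#' @return A `cap_pca`: list with `loadings`, `scores` (tibble), `var_explained`
#'   (%), `day_loading_r` (tibble `component`, `r`), `sdev`, `center`, `scale`.
#' @export
neural_pca <- function(features, n_components = 3L, standardize = TRUE) {
  x <- feature_values(features)
  if (nrow(x) <= n_components) abort("need more subjects than components")
  keep <- apply(x, 2L, sd) > 0
  pc <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = standardize)
  pc <- fix_pca_signs(pc)
  n_components <- min(n_components, ncol(pc$rotation))
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)

  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  cols <- rownames(load)
  day_of <- ifelse(grepl("_d1$", cols), 1L, ifelse(grepl("_d2$", cols), 2L, NA))
  day_r <- purrr::map_dfr(seq_len(n_components), function(j) {
    v1 <- load[which(day_of == 1L), j]
    v2 <- load[which(day_of == 2L), j]
    r <- if (length(v1) && length(v1) == length(v2) &&
             sd(v1) > 0 && sd(v2) > 0) {
      # pair columns by stripping the day suffix
      stem1 <- sub("_d1$", "", names(v1)); stem2 <- sub("_d2$", "", names(v2))
      cor(v1, v2[match(stem1, stem2)])
    } else NA_real_
    tibble::tibble(component = j, r = r)
  })

  scores <- tibble::as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  names(scores) <- paste0("PC", seq_len(n_components))
  scores <- dplyr::bind_cols(tibble::tibble(subject_id = rownames(x)), scores)

  structure(list(loadings = load, scores = scores,
                 var_explained = ve[seq_len(n_components)],
                 var_explained_all = ve,
                 day_loading_r = day_r,
                 sdev = pc$sdev, rotation = pc$rotation,
                 center = pc$center, scale = pc$scale),
            class = "cap_pca")
}

# Deterministic sign convention: largest-|loading| entry of each PC positive.
fix_pca_signs <- function(pc) {
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  pc
}

#' @export
print.cap_pca <- function(x, ...) {
  cat(sprintf("<cap_pca> %d components; variance explained: %s\n",
              length(x$var_explained),
              paste(sprintf("%.1f%%", x$var_explained), collapse = ", ")))
  invisible(x)
}
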