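#' Aggregate CAPs across permutations into a basis set
#'
#' Collects the centroids of every successful (permutation, split) entry
#' whose estimated k equals `k`, stacks them into a `(k * h) x P` array,
#' groups them into `k` clusters by agglomerative hierarchical clustering
#' (Ward linkage, Euclidean distance), averages parcel-wise within each
#' cluster and z-scores each resulting pattern across parcels (mean 0, SD 1
#' over the whole brain).
#'
#' @param ledger A `cap_ledger`.
#' @param k The solution size to aggregate.
#' @param splits Which splits to pool (default both, giving the group- and
#'   permutation-average basis; pass `1` or `2` for per-split bases).
#' @param labels Optional label vector of length `k`; defaults to
#'   `C1..Ck` ordered by descending cluster size.
#'
#' @return A `cap_basis`: list with `patterns` (k x P, z-scored), `labels`,
#'   `k`, `n_contributing` (permutation entries pooled), `cluster_sizes`.
#' @export
build_basis_set <- function(ledger, k, splits = c(1L, 2L), labels = NULL) {
  sel <- ledger[ledger$ok & ledger$k_hat == k & ledger$split %in% splits, ]
  if (nrow(sel) < 2L) {
    abort(sprintf("need >= 2 permutation entries with k_hat = %d (found %d)",
                  k, nrow(sel)))
  }
  stacked <- do.call(rbind, lapply(sel$capset, function(cs) cs$centroids))
  hc <- hclust(dist(stacked), method = "ward.D2")
  cl <- cutree(hc, k = k)
  sizes <- tabulate(cl, k)
  if (any(sizes < 0.01 * nrow(stacked))) {
    warn("a basis cluster captures < 1% of pooled centroids (unstable basis)")
  }
  ord <- order(sizes, decreasing = TRUE)
  patterns <- t(vapply(ord, function(j) {
    m <- colMeans(stacked[cl == j, , drop = FALSE])
    (m - mean(m)) / sd(m)
  }, numeric(ncol(stacked))))
  labels <- labels %||% paste0("C", seq_len(k))
  if (length(labels) != k) abort("`labels` must have length k")
  rownames(patterns) <- labels
  structure(list(patterns = patterns, labels = labels, k = k,
                 n_contributing = nrow(sel), cluster_sizes = sizes[ord]),
            class = "cap_basis")
}

#' @export
print.cap_basis <- function(x, ...) {
  cat(sprintf("<cap_basis> k = %d (%s), %d parcels, %d contributing entries\n",
              x$k, paste(x$labels, collapse = ", "), ncol(x$patterns),
              x$n_contributing))
  invisible(x)
}

#' Relabel a basis set against reference patterns
#'
#' Convenience for synthetic studies: renames basis CAPs by their greedy
#' one-to-one match to a reference pattern matrix (e.g. the generator's
#' ground truth), so estimated CAPs carry the planted state names.
#'
#' @param basis A `cap_basis`.
#' @param reference Named/rownamed K x P matrix of reference patterns,
#'   `K >= basis$k`.
#'
#' @return The basis with `labels`/rownames replaced.
#' @export
label_basis_set <- function(basis, reference) {
  est <- new_capset(basis$patterns, rep(1L, basis$k), NA_real_)
  ref <- structure(list(patterns = as.matrix(reference),
                        labels = rownames(reference), k = nrow(reference)),
                   class = "cap_basis")
  m <- match_caps(est, ref)
  basis$labels <- m$labels
  rownames(basis$patterns) <- m$labels
  basis
}

#' Match estimated CAPs one-to-one to basis CAPs
#'
#' Computes the full estimated x basis Pearson (or Spearman) correlation
#' matrix over parcels and assigns a one-to-one labeling greedily: the
#' globally largest unused (estimated, basis) pair is taken repeatedly until
#' every estimated CAP is labeled. A tie at machine precision breaks toward
#' the lower basis index.
#'
#' @param estimated A `cap_set` (or `cap_basis`) with `estimated$k <= basis$k`.
#' @param basis A `cap_basis`.
#' @param method `"pearson"` (default) or `"spearman"`.
#'
#' @return List with `labels` (basis label per estimated CAP), `assignment`
#'   tibble (`estimated`, `basis`, `label`, `r`), `r_matrix`, and `best_r`
#'   (per-estimated-CAP maximum correlation, for marginal summaries).
#' @export
match_caps <- function(estimated, basis, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  est <- if (inherits(estimated, "cap_basis")) estimated$patterns else estimated$centroids
  if (nrow(est) > basis$k) abort("estimated k must be <= basis k")
  r <- cor(t(est), t(basis$patterns), method = method)
  dimnames(r) <- list(NULL, basis$labels)
  avail_e <- rep(TRUE, nrow(r)); avail_b <- rep(TRUE, ncol(r))
  pairs <- list()
  for (step in seq_len(nrow(r))) {
    sub <- r
    sub[!avail_e, ] <- -Inf
    sub[, !avail_b] <- -Inf
    best <- which(sub == max(sub), arr.ind = TRUE)
    # ties: lower basis index, then lower estimated index
    best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
    lab <- basis$labels[best[2]]
    pairs[[step]] <- tibble::tibble(
      estimated = unname(best[1]), basis = unname(best[2]),
      label = lab, r = r[best[1], best[2]]
    )
    avail_e[best[1]] <- FALSE
    avail_b[best[2]] <- FALSE
  }
  assignment <- dplyr::arrange(dplyr::bind_rows(pairs), .data$estimated)
  list(labels = assignment$label,
       assignment = assignment,
       r_matrix = r,
       best_r = apply(r, 1L, max))
}

#' Per-subject CAP-preference statistic (delta occurrence)
#'
#' For each subject and each split, counts the permutations (among those in
#' which the subject was a member of that split) whose estimated k equalled
#' `k_pair[1]` resp. `k_pair[2]`; the preference is
#' `delta = occurrence(k_hi) - occurrence(k_lo)`, averaged over the two
#' splits and z-scored across subjects. Permutation entries with k outside
#' `k_pair` count toward neither side. If every subject has the same mean
#' delta the z-score is undefined and zeros are returned with a warning.
#'
#' @param ledger A `cap_ledger`.
#' @param k_pair The two competing solution sizes, low then high
#'   (default `c(4, 5)`).
#'
#' @return Tibble with per-split occurrence counts, `delta_s1`, `delta_s2`,
#'   `delta_mean` and `delta_z`.
#' @export
occurrence_stats <- function(ledger, k_pair = c(4L, 5L)) {
  ok <- ledger[ledger$ok, ]
  counts <- purrr::map_dfr(seq_len(nrow(ok)), function(i) {
    tibble::tibble(subject_id = ok$members[[i]], split = ok$split[i],
                   k_hat = ok$k_hat[i])
  })
  base <- dplyr::group_by(counts, .data$subject_id, .data$split) |>
    dplyr::summarise(
      occ_lo = sum(.data$k_hat == k_pair[1]),
      occ_hi = sum(.data$k_hat == k_pair[2]),
      .groups = "drop"
    ) |>
    dplyr::mutate(delta = .data$occ_hi - .data$occ_lo)
  wide <- tidyr::pivot_wider(
    base, id_cols = "subject_id", names_from = "split",
    values_from = c("occ_lo", "occ_hi", "delta"),
    values_fill = 0
  )
  # subjects can miss one split entirely across few permutations
  for (col in c("occ_lo_1", "occ_hi_1", "delta_1", "occ_lo_2", "occ_hi_2", "delta_2")) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  out <- dplyr::transmute(
    wide,
    subject_id = .data$subject_id,
    occ4_s1 = .data$occ_lo_1, occ5_s1 = .data$occ_hi_1,
    occ4_s2 = .data$occ_lo_2, occ5_s2 = .data$occ_hi_2,
    delta_s1 = .data$delta_1, delta_s2 = .data$delta_2,
    delta_mean = (.data$delta_1 + .data$delta_2) / 2
  )
  s <- sd(out$delta_mean)
  if (is.na(s) || s == 0) {
    warn("delta occurrence is constant across subjects; delta_z set to 0")
    out$delta_z <- 0
  } else {
    out$delta_z <- as.numeric(scale(out$delta_mean))
  }
  out
}

#' Cross-split similarity of basis sets
#'
#' Builds one basis per split for the same `k` and reports the greedy
#' one-to-one matched correlations between them, a reproducibility check of
#' the basis construction.
#'
#' @param ledger A `cap_ledger`.
#' @param k Solution size.
#'
#' @return Tibble with the matched pairs and their Pearson r.
#' @export
basis_cross_split_similarity <- function(ledger, k) {
  b1 <- build_basis_set(ledger, k, splits = 1L)
  b2 <- build_basis_set(ledger, k, splits = 2L)
  m <- match_caps(b1, b2)
  m$assignment
}
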