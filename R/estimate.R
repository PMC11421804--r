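#' Split subjects into two disjoint equal halves
#'
#' With an odd number of subjects one subject, chosen uniformly at random, is
#' excluded so both halves have exactly `floor(N / 2)` members.
#'
#' @param subject_ids Character vector of subject ids (>= 4).
#' @param seed Optional seed.
#'
#' @return List with character vectors `split1`, `split2` and `excluded`.
#' @export
split_half <- function(subject_ids, seed = NULL) {
  subject_ids <- as.character(subject_ids)
  n <- length(subject_ids)
  if (n < 4L) abort("need at least 4 subjects to split")
  half <- n %/% 2L
  with_seed_(seed, {
    perm <- sample(subject_ids)
    list(split1 = sort(perm[seq_len(half)]),
         split2 = sort(perm[half + seq_len(half)]),
         excluded = sort(perm[seq_len(n) > 2L * half]))
  })
}

# k-means++ seeding: centers sampled proportional to squared distance from
# the nearest already-chosen center.
kmeanspp_init <- function(x, k, seed = NULL, x2 = rowSums(x^2)) {
  with_seed_(seed, {
    n <- nrow(x)
    centers <- matrix(NA_real_, k, ncol(x))
    idx <- sample.int(n, 1L)
    centers[1L, ] <- x[idx, ]
    d2 <- pmax(0, x2 - 2 * drop(x %*% centers[1L, ]) + sum(centers[1L, ]^2))
    for (j in seq_len(k - 1L) + 1L) {
      if (all(d2 <= 0)) {
        idx <- sample.int(n, 1L)
      } else {
        idx <- sample.int(n, 1L, prob = d2)
      }
      centers[j, ] <- x[idx, ]
      d2_j <- pmax(0, x2 - 2 * drop(x %*% centers[j, ]) + sum(centers[j, ]^2))
      d2 <- pmin(d2, d2_j)
    }
    centers
  })
}

# Lloyd iterations from given centers. Converges when the relative decrease
# of inertia falls below `tol` (or assignments imply no further change),
# capped at `max_iter`. Returns NULL if a cluster empties.
lloyd_iterate <- function(x, centers, x2, max_iter = 1000L, tol = 1e-4) {
  sum_x2 <- sum(x2)
  inertia_prev <- Inf
  cl <- NULL
  for (it in seq_len(max_iter)) {
    # argmin ||x - c||^2 == argmax x.c - ||c||^2 / 2
    score <- x %*% t(centers)
    score <- sweep(score, 2L, 0.5 * rowSums(centers^2), "-")
    cl <- max.col(score, ties.method = "first")
    sizes <- tabulate(cl, nrow(centers))
    if (any(sizes == 0L)) return(NULL)
    centers <- rowsum(x, cl) / sizes
    # centers are now the within-cluster means, so the within-cluster SS is
    # sum |x|^2 - sum_j n_j |c_j|^2
    inertia <- sum_x2 - sum(sizes * rowSums(centers^2))
    if (is.finite(inertia_prev) &&
        (inertia_prev - inertia) <= tol * inertia_prev) break
    inertia_prev <- inertia
  }
  list(cluster = cl, centers = centers, size = sizes,
       tot.withinss = inertia, iter = it)
}

# k-means fit: k-means++ init then Lloyd iterations (max 1000, relative
# inertia tolerance 1e-4), repeated n_init times keeping the lowest-inertia
# solution. An empty cluster triggers a re-run with a derived seed, at most
# `retries` extra attempts.
fit_kmeans <- function(x, k, seed, n_init = 5L, max_iter = 1000L, tol = 1e-4,
                       retries = 5L) {
  seeds <- derive_seeds(seed, n_init + retries)
  x2 <- rowSums(x^2)
  best <- NULL
  done <- 0L
  for (s in seeds) {
    init <- kmeanspp_init(x, k, s, x2 = x2)
    km <- lloyd_iterate(x, init, x2, max_iter = max_iter, tol = tol)
    if (!is.null(km)) {
      done <- done + 1L
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (done >= n_init) break
  }
  if (is.null(best)) {
    abort(sprintf("k-means with k = %d produced an empty cluster after %d attempts",
                  k, n_init + retries))
  }
  best
}

new_capset <- function(centroids, frame_counts, inertia, provenance = NULL) {
  structure(list(centroids = centroids, k = nrow(centroids),
                 frame_counts = frame_counts, inertia = inertia,
                 provenance = provenance),
            class = "cap_set")
}

#' @export
print.cap_set <- function(x, ...) {
  cat(sprintf("<cap_set> k = %d, %d parcels, %s frames\n",
              x$k, ncol(x$centroids), format(sum(x$frame_counts))))
  invisible(x)
}

#' Scan k-means solutions over a range of k
#'
#' For each `k` in `k_range`, fits k-means (k-means++ initialisation, Lloyd
#' iterations capped at 1000) to the pooled scrub-masked frames and records
#' the centroids and the mean silhouette width. Silhouettes are computed on a
#' seeded uniform subsample of frames (default 2000) to stay tractable on
#' large pools; the subsample size is recorded.
#'
#' @param pooled_frames frames x parcels numeric matrix (already scrubbed).
#' @param k_range Contiguous integer range of k values, min >= 2.
#' @param seed Seed controlling initialisation and subsampling.
#' @param silhouette_subsample Max frames used for the silhouette (default 2000).
#' @param n_init Number of k-means++ restarts per k; the lowest-inertia
#'   solution is kept (default 5).
#'
#' @return A `cap_kscan`: tibble with columns `k`, `silhouette`, `capset`
#'   (list), plus attributes.
#' @export
scan_k <- function(pooled_frames, k_range = 2:15, seed = NULL,
                   silhouette_subsample = 2000L, n_init = 5L) {
  x <- as.matrix(pooled_frames)
  k_range <- sort(as.integer(k_range))
  if (min(k_range) < 2L) abort("`k_range` must start at 2 or above")
  if (nrow(x) < max(k_range) * 10L) {
    abort(sprintf("need at least %d frames for k up to %d",
                  max(k_range) * 10L, max(k_range)))
  }
  seeds <- derive_seeds(seed %||% 1L, length(k_range) + 1L)
  n_sub <- min(nrow(x), as.integer(silhouette_subsample))
  sub_idx <- with_seed_(seeds[length(seeds)], sample.int(nrow(x), n_sub))
  d_sub <- dist(x[sub_idx, , drop = FALSE])

  rows <- purrr::map2(k_range, seeds[seq_along(k_range)], function(k, s) {
    km <- fit_kmeans(x, k, s, n_init = n_init)
    sil <- cluster::silhouette(km$cluster[sub_idx], d_sub)
    tibble::tibble(
      k = k,
      silhouette = mean(sil[, "sil_width"]),
      capset = list(new_capset(km$centers, km$size, km$tot.withinss)),
      cluster = list(km$cluster)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "silhouette_subsample") <- n_sub
  class(out) <- c("cap_kscan", class(out))
  out
}

#' Pick the optimal k by the silhouette-elbow (knee) rule
#'
#' Applies a Kneedle-style rule to the silhouette-versus-k curve: both axes
#' are range-normalized to `[0, 1]` and the knee is the point of maximum
#' positive distance of the curve above the straight line joining its
#' endpoints (the orientation for a decreasing curve whose early points fall
#' off slowly before a sharp drop). Ties break toward smaller k. When no
#' point rises above the chord (e.g. a strictly linear decline), the rule
#' falls back to the silhouette argmax with a warning.
#'
#' @param silhouette_by_k A `cap_kscan`, or a data frame with columns `k` and
#'   `silhouette`, or a named numeric vector (names = k).
#'
#' @return Integer k-hat with attributes `method` (`"knee"` or `"argmax"`)
#'   and `distance` (the normalized chord distances).
#' @export
estimate_k <- function(silhouette_by_k) {
  if (is.data.frame(silhouette_by_k)) {
    k <- silhouette_by_k$k
    s <- silhouette_by_k$silhouette
  } else {
    k <- as.integer(names(silhouette_by_k))
    s <- as.numeric(silhouette_by_k)
  }
  ord <- order(k)
  k <- k[ord]; s <- s[ord]
  if (length(k) < 3L || any(!is.finite(s))) {
    abort("need >= 3 finite silhouette scores to locate a knee")
  }
  xn <- (k - min(k)) / (max(k) - min(k))
  rng <- max(s) - min(s)
  yn <- if (rng > 0) (s - min(s)) / rng else rep(0, length(s))
  # chord from (0, y_first) to (1, y_last) in normalized coordinates
  chord <- yn[1] + (yn[length(yn)] - yn[1]) * xn
  d <- yn - chord
  if (max(d) > 1e-8) {
    khat <- k[which.max(d)]  # which.max takes the first maximum: smaller k
    method <- "knee"
  } else {
    warn("no knee above the endpoint chord; falling back to silhouette argmax")
    khat <- k[which.max(s)]
    method <- "argmax"
  }
  structure(as.integer(khat), method = method,
            distance = setNames(d, k))
}

# Pool scrub-masked frames for a set of subjects (both days), remembering
# which (subject, day, run, frame) each pooled row came from.
pool_frames <- function(cohort, subject_ids, fd_threshold = 0.5) {
  blocks <- list(); maps <- list()
  for (id in subject_ids) {
    for (day in cohort_days(cohort)) {
      ts <- cohort_series(cohort, id, day)
      if (is.null(ts)) next
      keep <- scrub_mask(ts, fd_threshold)
      idx <- which(keep)
      blocks[[length(blocks) + 1L]] <- ts$data[idx, , drop = FALSE]
      maps[[length(maps) + 1L]] <- tibble::tibble(
        subject_id = id, day = day, frame = idx,
        run = run_id_vector(ts)[idx]
      )
    }
  }
  list(frames = do.call(rbind, blocks), map = dplyr::bind_rows(maps))
}

#' Run the shuffled split-half permutation engine
#'
#' For each permutation: subjects are split into two disjoint halves; within
#' each split, all scrub-masked frames (both days) are pooled by temporal
#' concatenation; k-means solutions are scanned over `k_range`; k-hat is
#' picked by the silhouette-elbow rule; and per-subject-per-day temporal
#' metrics are computed from the k-hat solution's frame assignments.
#' Per-permutation seeds derive deterministically from `base_seed`, so the
#' ledger is reproducible and permutations are order-independent. A failed
#' permutation is recorded with its error, never silently dropped.
#'
#' @param cohort A preprocessed [cap_cohort()].
#' @param n_perm Number of permutations (>= 1).
#' @param k_range Range of k to scan (default 2:15).
#' @param base_seed Seed for the whole engine.
#' @param fd_threshold Scrubbing threshold in mm (default 0.5).
#' @param silhouette_subsample,n_init Passed to [scan_k()].
#'
#' @return A `cap_ledger`: tibble with one row per (permutation, split) and
#'   columns `perm`, `split`, `members` (list), `k_hat`, `silhouettes`
#'   (list), `capset` (list), `metrics` (list of per-subject-day tibbles),
#'   `ok`, `error`.
#' @export
run_permutations <- function(cohort, n_perm, k_range = 2:15, base_seed = 1L,
                             fd_threshold = 0.5, silhouette_subsample = 2000L,
                             n_init = 5L) {
  stopifnot(inherits(cohort, "cap_cohort"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) abort("`n_perm` must be >= 1")
  ids <- cohort$subjects$subject_id
  perm_seeds <- derive_seeds(base_seed, n_perm)

  rows <- purrr::map(seq_len(n_perm), function(p) {
    sseeds <- derive_seeds(perm_seeds[p], 3L)
    halves <- split_half(ids, sseeds[1])
    purrr::map(1:2, function(sp) {
      members <- halves[[sp]]
      res <- tryCatch({
        pooled <- pool_frames(cohort, members, fd_threshold)
        scan <- scan_k(pooled$frames, k_range, seed = sseeds[1L + sp],
                       silhouette_subsample = silhouette_subsample,
                       n_init = n_init)
        khat <- estimate_k(scan)
        sel <- scan[scan$k == as.integer(khat), ]
        capset <- sel$capset[[1]]
        capset$provenance <- list(perm = p, split = sp)
        metrics <- metrics_from_assignments(
          pooled$map, sel$cluster[[1]], n_states = capset$k
        )
        tibble::tibble(
          perm = p, split = sp, members = list(members),
          k_hat = as.integer(khat),
          k_method = attr(khat, "method"),
          silhouettes = list(tibble::tibble(k = scan$k, silhouette = scan$silhouette)),
          capset = list(capset), metrics = list(metrics),
          ok = TRUE, error = NA_character_
        )
      }, error = function(e) {
        tibble::tibble(
          perm = p, split = sp, members = list(members),
          k_hat = NA_integer_, k_method = NA_character_,
          silhouettes = list(NULL), capset = list(NULL), metrics = list(NULL),
          ok = FALSE, error = conditionMessage(e)
        )
      })
      res
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  attr(out, "k_range") <- k_range
  attr(out, "fd_threshold") <- fd_threshold
  attr(out, "base_seed") <- base_seed
  attr(out, "n_subjects") <- length(ids)
  class(out) <- c("cap_ledger", class(out))
  out
}

#' Occurrence rates of each estimated k across a ledger
#'
#' @param ledger A `cap_ledger`.
#' @return Tibble with `k_hat`, `n`, `rate` over successful (perm, split) entries.
#' @export
k_occurrence <- function(ledger) {
  ok <- ledger[ledger$ok, ]
  dplyr::count(tibble::as_tibble(ok), .data$k_hat, name = "n") |>
    dplyr::mutate(rate = .data$n / sum(.data$n))
}
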