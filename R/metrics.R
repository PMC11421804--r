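#' Assign frames to CAP states
#'
#' Assigns each kept (non-scrubbed) frame of a subject-day to a CAP.
#' `mode = "cluster"` uses the k-means criterion (nearest centroid,
#' Euclidean); `mode = "correlation"` uses the maximum Pearson correlation
#' with the CAP patterns and also returns the per-frame maximum r.
#' A zero-variance frame has no defined correlation and falls back to the
#' Euclidean rule, flagged in the output.
#'
#' @param ts A [parcel_ts()].
#' @param mask Logical keep-mask from [scrub_mask()].
#' @param caps A `cap_set` (centroids) or `cap_basis` (patterns).
#' @param mode `"cluster"` or `"correlation"`.
#'
#' @return A `state_seq`: list with `subject_id`, `day`, `labels` (integer
#'   CAP index per kept frame), `kept_idx`, `run`, and for correlation mode
#'   `max_r` and `fallback` flags.
#' @export
assign_frames <- function(ts, mask, caps, mode = c("cluster", "correlation")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ts, "parcel_ts"))
  centers <- if (inherits(caps, "cap_basis")) caps$patterns else caps$centroids
  if (ncol(centers) != ncol(ts$data)) abort("parcel count mismatch")
  idx <- which(mask)
  x <- ts$data[idx, , drop = FALSE]

  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) + outer(rep(1, nrow(x)), rowSums(centers^2))
  lab_eu <- max.col(-d2, ties.method = "first")

  max_r <- NULL; fallback <- NULL
  if (mode == "correlation") {
    sds <- apply(x, 1L, sd)
    fallback <- sds == 0
    r <- matrix(NA_real_, nrow(x), nrow(centers))
    if (any(!fallback)) {
      r[!fallback, ] <- suppressWarnings(
        cor(t(x[!fallback, , drop = FALSE]), t(centers)))
    }
    labels <- lab_eu
    if (any(!fallback)) {
      r_safe <- r[!fallback, , drop = FALSE]
      r_safe[is.na(r_safe)] <- -Inf
      labels[!fallback] <- max.col(r_safe, ties.method = "first")
    }
    max_r <- rep(NA_real_, nrow(x))
    max_r[!fallback] <- r[cbind(which(!fallback), labels[!fallback])]
  } else {
    labels <- lab_eu
  }

  structure(list(subject_id = ts$subject_id, day = ts$day,
                 labels = labels, kept_idx = idx,
                 run = run_id_vector(ts)[idx],
                 max_r = max_r, fallback = fallback),
            class = "state_seq")
}

#' @export
print.state_seq <- function(x, ...) {
  cat(sprintf("<state_seq> subject %s day %d: %d kept frames, %d states\n",
              x$subject_id, x$day, length(x$labels),
              length(unique(x$labels))))
  invisible(x)
}

#' Run-length segments of a state sequence
#'
#' Run-length encodes the kept-frame label sequence. Because scrubbed frames
#' are already absent, the frames flanking a scrubbed gap merge into one
#' segment when they share a CAP state. Segments never cross a run boundary
#' when `run` ids are supplied (runs are not contiguous in time).
#'
#' @param labels Integer/character label vector (kept frames only), or a
#'   `state_seq`.
#' @param run Optional per-kept-frame run id; segments break where it changes.
#'
#' @return Tibble with `label`, `length` (#TR) and `run`.
#' @export
extract_segments <- function(labels, run = NULL) {
  if (inherits(labels, "state_seq")) {
    run <- labels$run
    labels <- labels$labels
  }
  if (length(labels) == 0L) {
    return(tibble::tibble(label = integer(), length = integer(), run = integer()))
  }
  run <- run %||% rep(1L, length(labels))
  out <- list()
  for (r in unique(run)) {
    rl <- rle(labels[run == r])
    out[[length(out) + 1L]] <- tibble::tibble(
      label = rl$values, length = rl$lengths, run = r
    )
  }
  dplyr::bind_rows(out)
}

#' Temporal CAP metrics for one subject-day
#'
#' Computes, for every CAP in `cap_labels`: fractional occupancy
#' `fo = kept frames in the state / total kept frames` (so FO sums to 1
#' across CAPs), the within-subject mean dwell time `mean_dt` (mean segment
#' length, #TR), and `var_dt`, the standard deviation of segment lengths
#' (population SD, so a single segment gives 0). CAPs never visited get
#' zeros for all three, the convention used throughout the feature matrix.
#'
#' @param seq A `state_seq`, or an integer/character label vector.
#' @param cap_labels Full label set the metrics are reported over.
#' @param run Optional run ids when `seq` is a bare vector.
#' @param var_dt_type `"population"` (default) or `"sample"` SD.
#'
#' @return Tibble with `state`, `fo`, `mean_dt`, `var_dt`, `n_segments`.
#' @export
compute_metrics <- function(seq, cap_labels, run = NULL,
                            var_dt_type = c("population", "sample")) {
  var_dt_type <- match.arg(var_dt_type)
  if (inherits(seq, "state_seq")) {
    run <- seq$run
    labels <- seq$labels
  } else {
    labels <- seq
  }
  if (length(labels) == 0L) {
    warn("empty state sequence: all metrics zero")
    return(tibble::tibble(state = cap_labels, fo = 0, mean_dt = 0,
                          var_dt = 0, n_segments = 0L))
  }
  segs <- extract_segments(labels, run)
  total <- length(labels)
  purrr::map_dfr(cap_labels, function(s) {
    len <- segs$length[segs$label == s]
    if (length(len) == 0L) {
      return(tibble::tibble(state = s, fo = 0, mean_dt = 0, var_dt = 0,
                            n_segments = 0L))
    }
    vd <- if (length(len) == 1L) 0 else {
      if (var_dt_type == "population") {
        sqrt(mean((len - mean(len))^2))
      } else {
        sd(len)
      }
    }
    tibble::tibble(state = s, fo = sum(len) / total, mean_dt = mean(len),
                   var_dt = vd, n_segments = length(len))
  })
}

# Per-subject-day metrics from pooled-frame k-means assignments
# (used inside run_permutations; states are split-local cluster ids).
metrics_from_assignments <- function(map, cluster, n_states) {
  map$state <- cluster
  dplyr::group_by(map, .data$subject_id, .data$day) |>
    dplyr::group_modify(function(df, key) {
      compute_metrics(df$state, cap_labels = seq_len(n_states), run = df$run)
    }) |>
    dplyr::ungroup()
}

#' Average temporal metrics across permutations
#'
#' Takes relabeled per-permutation metrics (see [relabel_ledger_metrics()])
#' and averages each subject x CAP x day cell over the permutations in which
#' the subject appears. Two conventions for a CAP absent from a
#' permutation's solution (e.g. CAP III under a 4-CAP split): with
#' `absent_as_zero = TRUE` (the feature-matrix convention) absent
#' permutations contribute zeros; with `FALSE` (the reliability convention)
#' they are excluded from the average. `n_perm` counts the permutations the
#' subject appeared in; `n_present` those whose solution contained the CAP.
#'
#' @param per_perm Tibble with columns `perm`, `subject_id`, `day`, `state`,
#'   `fo`, `mean_dt`, `var_dt`, `n_segments`.
#' @param cap_labels Full label set of the aggregate.
#' @param absent_as_zero Convention for absent CAPs (default `TRUE`).
#'
#' @return Tibble with `subject_id`, `day`, `state`, averaged `fo`,
#'   `mean_dt`, `var_dt`, plus `n_perm` and `n_present`.
#' @export
aggregate_metrics <- function(per_perm, cap_labels = NULL,
                              absent_as_zero = TRUE) {
  cap_labels <- cap_labels %||% sort(unique(per_perm$state))
  appearances <- dplyr::distinct(per_perm, .data$perm, .data$subject_id, .data$day)
  full <- tidyr::expand_grid(
    dplyr::distinct(appearances, .data$perm, .data$subject_id, .data$day),
    state = cap_labels
  )
  joined <- dplyr::left_join(
    full, per_perm, by = c("perm", "subject_id", "day", "state")
  )
  joined$present <- !is.na(joined$fo)
  if (absent_as_zero) {
    joined <- tidyr::replace_na(joined, list(fo = 0, mean_dt = 0, var_dt = 0,
                                             n_segments = 0L))
  }
  dplyr::group_by(joined, .data$subject_id, .data$day, .data$state) |>
    dplyr::summarise(
      n_perm = dplyr::n(),
      n_present = sum(.data$present),
      fo = mean(.data$fo, na.rm = TRUE),
      mean_dt = mean(.data$mean_dt, na.rm = TRUE),
      var_dt = mean(.data$var_dt, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(dplyr::across(c("fo", "mean_dt", "var_dt"),
                                ~ ifelse(is.nan(.x), 0, .x)))
}

#' Relabel ledger metrics into basis-CAP label space
#'
#' Each (permutation, split) entry's split-local cluster ids are mapped to
#' basis-CAP labels by matching its centroids to the basis patterns
#' ([match_caps()]), making metrics comparable across permutations.
#'
#' @param ledger A `cap_ledger`.
#' @param basis A `cap_basis`.
#'
#' @return Tibble of per-permutation metrics with `state` = basis label.
#' @export
relabel_ledger_metrics <- function(ledger, basis) {
  ok <- ledger[ledger$ok & ledger$k_hat <= basis$k, ]
  if (nrow(ok) == 0L) abort("no ledger entries with k_hat <= basis k")
  purrr::map_dfr(seq_len(nrow(ok)), function(i) {
    m <- match_caps(ok$capset[[i]], basis)
    met <- ok$metrics[[i]]
    met$state <- m$labels[met$state]
    met$perm <- ok$perm[i]
    met$split <- ok$split[i]
    met
  })
}
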