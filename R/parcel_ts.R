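#' Parcellated BOLD time series for one subject-day
#'
#' Container for a frames x parcels signal matrix together with its run
#' structure and per-frame framewise displacement (FD). Runs are stored as
#' 1-based inclusive `[start, end]` frame intervals that are disjoint, ordered
#' and tile `1:n_frames`; FD has one value (mm) per frame.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param day Session day, `1` or `2`.
#' @param data Numeric matrix, frames in rows, parcels in columns.
#' @param runs Tibble/data frame with columns `run`, `start`, `end`
#'   (1-based inclusive frame intervals). Defaults to a single run.
#' @param fd Numeric vector of framewise displacement (mm), one per frame.
#' @param tr Repetition time in seconds per frame.
#'
#' @return An object of class `parcel_ts`.
#' @export
parcel_ts <- function(subject_id, day, data, runs = NULL, fd, tr = 0.72) {
  data <- as.matrix(data)
  if (!is.numeric(data)) abort("`data` must be a numeric matrix")
  n <- nrow(data)
  if (is.null(runs)) {
    runs <- tibble::tibble(run = 1L, start = 1L, end = n)
  }
  runs <- tibble::as_tibble(runs)
  runs$run <- as.integer(runs$run)
  runs$start <- as.integer(runs$start)
  runs$end <- as.integer(runs$end)
  out <- structure(
    list(
      subject_id = as.character(subject_id),
      day = as.integer(day),
      data = data,
      runs = runs,
      fd = as.numeric(fd),
      tr = as.numeric(tr)
    ),
    class = "parcel_ts"
  )
  validate_parcel_ts(out)
}

validate_parcel_ts <- function(x) {
  n <- nrow(x$data)
  if (!x$day %in% c(1L, 2L)) abort("`day` must be 1 or 2")
  if (length(x$fd) != n) {
    abort(sprintf("fd length (%d) must equal n_frames (%d) for subject %s day %d",
                  length(x$fd), n, x$subject_id, x$day))
  }
  r <- x$runs[order(x$runs$start), , drop = FALSE]
  if (r$start[1] != 1L || r$end[nrow(r)] != n ||
      (nrow(r) > 1 && any(r$start[-1] != r$end[-nrow(r)] + 1L))) {
    abort(sprintf("run intervals must be disjoint, ordered and tile 1:%d", n))
  }
  if (any(r$end < r$start)) abort("run intervals must be non-empty")
  x
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("<parcel_ts> subject %s, day %d: %d frames x %d parcels, %d run(s), TR = %gs\n",
              x$subject_id, x$day, nrow(x$data), ncol(x$data), nrow(x$runs), x$tr))
  invisible(x)
}

n_frames <- function(ts) nrow(ts$data)

# per-frame run id vector for a parcel_ts
run_id_vector <- function(ts) {
  out <- integer(n_frames(ts))
  for (i in seq_len(nrow(ts$runs))) {
    out[ts$runs$start[i]:ts$runs$end[i]] <- ts$runs$run[i]
  }
  out
}

#' A cohort of parcellated time series
#'
#' Bundles one [parcel_ts()] per subject-day with the subject covariate table.
#' Series are stored in deterministic order (subject, then day).
#'
#' @param series List of [parcel_ts()] objects.
#' @param subjects Tibble with at least `subject_id`; typically also
#'   `age` and `sex`.
#'
#' @return An object of class `cap_cohort`.
#' @export
cap_cohort <- function(series, subjects) {
  subjects <- tibble::as_tibble(subjects)
  subjects$subject_id <- as.character(subjects$subject_id)
  ord <- order(vapply(series, function(s) s$subject_id, ""),
               vapply(series, function(s) s$day, 1L))
  series <- series[ord]
  names(series) <- vapply(series, function(s) paste(s$subject_id, s$day, sep = "."), "")
  p <- unique(vapply(series, function(s) ncol(s$data), 1L))
  if (length(p) != 1L) {
    abort(sprintf("all series must share one parcel count; found {%s}",
                  paste(p, collapse = ", ")))
  }
  structure(list(series = series, subjects = subjects, n_parcels = p),
            class = "cap_cohort")
}

#' @export
print.cap_cohort <- function(x, ...) {
  cat(sprintf("<cap_cohort> %d subjects, %d series, %d parcels\n",
              nrow(x$subjects), length(x$series), x$n_parcels))
  invisible(x)
}

cohort_subject_ids <- function(cohort) sort(unique(x = cohort$subjects$subject_id))

cohort_series <- function(cohort, subject_id, day) {
  cohort$series[[paste(subject_id, day, sep = ".")]]
}

cohort_days <- function(cohort) {
  sort(unique(vapply(cohort$series, function(s) s$day, 1L)))
}
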