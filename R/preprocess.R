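#' Frame-level preprocessing: dummy removal, per-run demeaning, reordering
#'
#' Drops the first `n_dummy` frames of every run (scanner equilibration
#' frames), removes the per-run per-parcel mean from the remaining signal,
#' then concatenates the runs in `run_order`. FD and run boundaries are
#' carried through consistently.
#'
#' @param ts A [parcel_ts()].
#' @param n_dummy Frames to drop at the start of every run (default 100).
#' @param run_order Integer permutation of the run ids giving the
#'   concatenation (acquisition) order. Defaults to `c(2, 1, 4, 3)` for
#'   4-run series and the stored order otherwise.
#'
#' @return A new [parcel_ts()] with `n_frames - n_runs * n_dummy` frames,
#'   each remaining run having per-parcel mean zero.
#' @export
preprocess_runs <- function(ts, n_dummy = 100L, run_order = NULL) {
  stopifnot(inherits(ts, "parcel_ts"))
  n_dummy <- as.integer(n_dummy)
  if (n_dummy < 0L) abort("`n_dummy` must be >= 0")
  run_ids <- ts$runs$run
  if (is.null(run_order)) {
    run_order <- if (length(run_ids) == 4L) c(2L, 1L, 4L, 3L) else run_ids
  }
  run_order <- as.integer(run_order)
  if (length(run_order) == 0L) abort("`run_order` must not be empty")
  if (!setequal(run_order, run_ids) || length(run_order) != length(run_ids)) {
    abort("`run_order` must be a permutation of the run ids")
  }

  pieces <- lapply(run_order, function(r) {
    row <- ts$runs[ts$runs$run == r, ]
    len <- row$end - row$start + 1L
    if (len <= n_dummy) {
      abort(sprintf("run %d has %d frames, not more than n_dummy = %d", r, len, n_dummy))
    }
    idx <- (row$start + n_dummy):row$end
    x <- ts$data[idx, , drop = FALSE]
    x <- sweep(x, 2L, colMeans(x), "-")
    list(run = r, data = x, fd = ts$fd[idx])
  })

  lens <- vapply(pieces, function(p) nrow(p$data), 1L)
  ends <- cumsum(lens)
  runs <- tibble::tibble(
    run = vapply(pieces, function(p) p$run, 1L),
    start = c(1L, head(ends, -1L) + 1L),
    end = ends
  )
  parcel_ts(
    subject_id = ts$subject_id, day = ts$day,
    data = do.call(rbind, lapply(pieces, `[[`, "data")),
    runs = runs,
    fd = unlist(lapply(pieces, `[[`, "fd")),
    tr = ts$tr
  )
}

#' Motion-scrubbing mask from framewise displacement
#'
#' Marks frames for exclusion when FD exceeds the threshold. The comparison
#' is strict: a frame with FD exactly at the threshold is kept. The mask
#' never modifies the data; downstream operations apply it at clustering and
#' metric time.
#'
#' @param ts A [parcel_ts()].
#' @param fd_threshold Scrubbing threshold in mm (default 0.5).
#'
#' @return Logical vector, `TRUE` for kept frames.
#' @export
scrub_mask <- function(ts, fd_threshold = 0.5) {
  stopifnot(inherits(ts, "parcel_ts"))
  stopifnot_scalar_number(fd_threshold, "fd_threshold", lower = 0)
  bad <- which(!is.finite(ts$fd))
  if (length(bad)) {
    abort(sprintf("non-finite FD at frame(s) %s for subject %s day %d",
                  paste(head(bad, 5), collapse = ", "), ts$subject_id, ts$day))
  }
  ts$fd <= fd_threshold
}
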