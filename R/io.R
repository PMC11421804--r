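#' Write a cohort to a directory of TSV files
#'
#' On-disk layout: one tab-delimited frames x parcels matrix per run
#' (header row = parcel ids), a one-column `fd` file per run, a
#' `manifest.tsv` (`subject_id`, `day`, `run`, `path`, `fd_path`, `tr`) and a
#' `subjects.tsv` covariate table.
#'
#' @param cohort A [cap_cohort()].
#' @param dir Output directory (created if missing).
#'
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cap_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (ts in cohort$series) {
    for (i in seq_len(nrow(ts$runs))) {
      r <- ts$runs[i, ]
      stem <- sprintf("sub-%s_day-%d_run-%d", ts$subject_id, ts$day, r$run)
      mat <- ts$data[r$start:r$end, , drop = FALSE]
      colnames(mat) <- colnames(ts$data) %||% paste0("p", seq_len(ncol(mat)))
      path <- file.path(dir, paste0(stem, "_bold.tsv"))
      fd_path <- file.path(dir, paste0(stem, "_fd.tsv"))
      readr::write_tsv(tibble::as_tibble(mat, .name_repair = "minimal"), path,
                       progress = FALSE)
      readr::write_tsv(tibble::tibble(fd = ts$fd[r$start:r$end]), fd_path,
                       progress = FALSE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        subject_id = ts$subject_id, day = ts$day, run = r$run,
        path = basename(path), fd_path = basename(fd_path), tr = ts$tr
      )
    }
  }
  readr::write_tsv(dplyr::bind_rows(rows), file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  readr::write_tsv(cohort$subjects, file.path(dir, "subjects.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Load a cohort from a directory of TSV files
#'
#' Reads the layout written by [write_cohort()]. Runs of one subject-day are
#' concatenated in run-id order with run boundaries recorded (acquisition
#' reordering is the job of [preprocess_runs()]). All matrices must share one
#' parcel count, and every run must have an FD series: FD is required, never
#' silently assumed zero.
#'
#' @param dir Directory containing `manifest.tsv` and `subjects.tsv`.
#'
#' @return A [cap_cohort()].
#' @export
load_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) abort(sprintf("no manifest.tsv under %s", dir))
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE)
  need <- c("subject_id", "day", "run", "path", "fd_path")
  if (!all(need %in% names(manifest))) {
    abort(sprintf("manifest.tsv must have columns %s", paste(need, collapse = ", ")))
  }
  manifest$subject_id <- as.character(manifest$subject_id)
  subjects <- readr::read_tsv(file.path(dir, "subjects.tsv"), show_col_types = FALSE)

  n_parcels <- NULL
  series <- list()
  for (key in split(manifest, paste(manifest$subject_id, manifest$day, sep = "."))) {
    key <- key[order(key$run), , drop = FALSE]
    mats <- list(); fds <- list()
    for (i in seq_len(nrow(key))) {
      m <- as.matrix(readr::read_tsv(file.path(dir, key$path[i]),
                                     show_col_types = FALSE))
      if (is.null(n_parcels)) n_parcels <- ncol(m)
      if (ncol(m) != n_parcels) {
        abort(sprintf("file %s has %d parcels; cohort has %d",
                      key$path[i], ncol(m), n_parcels))
      }
      fd_file <- file.path(dir, key$fd_path[i])
      if (!file.exists(fd_file)) {
        abort(sprintf("missing FD file %s (FD is required)", key$fd_path[i]))
      }
      fd <- readr::read_tsv(fd_file, show_col_types = FALSE)
      if (!"fd" %in% names(fd)) {
        abort(sprintf("FD file %s lacks an `fd` column (FD is required)", key$fd_path[i]))
      }
      if (nrow(fd) != nrow(m)) {
        abort(sprintf("FD length mismatch in %s", key$fd_path[i]))
      }
      mats[[i]] <- m; fds[[i]] <- fd$fd
    }
    lens <- vapply(mats, nrow, 1L)
    ends <- cumsum(lens)
    series[[length(series) + 1L]] <- parcel_ts(
      subject_id = key$subject_id[1], day = key$day[1],
      data = do.call(rbind, mats),
      runs = tibble::tibble(run = key$run, start = c(1L, head(ends, -1L) + 1L),
                            end = ends),
      fd = unlist(fds),
      tr = if ("tr" %in% names(key)) key$tr[1] else 0.72
    )
  }
  cap_cohort(series, subjects)
}
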