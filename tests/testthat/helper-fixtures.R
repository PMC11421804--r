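# shared fixtures and independent oracles

# small deterministic parcel_ts: frames x parcels = outer structure + optional fd
make_ts <- function(subject = "S1", day = 1, n_runs = 2, frames_per_run = 50,
                    n_parcels = 8, fd = NULL, seed = 1) {
  n <- n_runs * frames_per_run
  data <- withr::with_seed(seed, matrix(rnorm(n * n_parcels), n, n_parcels))
  ends <- cumsum(rep(frames_per_run, n_runs))
  parcel_ts(
    subject_id = subject, day = day, data = data,
    runs = tibble::tibble(run = seq_len(n_runs),
                          start = c(1L, head(ends, -1L) + 1L), end = ends),
    fd = fd %||% rep(0.1, n)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent oracle for FO / mean DT / var DT: explicit frame-by-frame scan
naive_metrics <- function(labels, cap_labels, run = NULL) {
  run <- run %||% rep(1L, length(labels))
  res <- list()
  for (s in cap_labels) {
    lens <- integer()
    cur <- 0L
    for (i in seq_along(labels)) {
      new_block <- i > 1 && run[i] != run[i - 1]
      if (labels[i] == s && !new_block && cur > 0L) {
        cur <- cur + 1L
      } else if (labels[i] == s) {
        if (cur > 0L) lens <- c(lens, cur)
        cur <- 1L
      } else {
        if (cur > 0L) lens <- c(lens, cur)
        cur <- 0L
      }
    }
    if (cur > 0L) lens <- c(lens, cur)
    if (length(lens) == 0L) {
      res[[as.character(s)]] <- c(fo = 0, mean_dt = 0, var_dt = 0, n_segments = 0)
    } else {
      res[[as.character(s)]] <- c(
        fo = sum(lens) / length(labels),
        mean_dt = mean(lens),
        var_dt = sqrt(mean((lens - mean(lens))^2)),
        n_segments = length(lens)
      )
    }
  }
  do.call(rbind, res)
}

# independent ICC(2,1) oracle through R's ANOVA machinery
anova_icc21 <- function(mat) {
  df <- data.frame(
    value = as.vector(mat),
    subject = factor(rep(seq_len(nrow(mat)), ncol(mat))),
    session = factor(rep(seq_len(ncol(mat)), each = nrow(mat)))
  )
  aov_tab <- anova(lm(value ~ subject + session, data = df))
  msr <- aov_tab["subject", "Mean Sq"]
  msc <- aov_tab["session", "Mean Sq"]
  mse <- aov_tab["Residuals", "Mean Sq"]
  n <- nrow(mat); k <- ncol(mat)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# exhaustive optimal one-to-one assignment by total correlation (k <= 4)
exhaustive_match <- function(r) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- NULL; best_val <- -Inf
  for (p in perms(seq_len(ncol(r)))) {
    sel <- p[seq_len(nrow(r))]
    val <- sum(r[cbind(seq_len(nrow(r)), sel)])
    if (val > best_val) { best_val <- val; best <- sel }
  }
  list(assignment = best, total = best_val)
}

# tiny cohort for fast pipeline-level tests
small_sim <- function(seed = 5, n_subjects = 12L, ...) {
  generate_cohort(sim_config(
    n_subjects = n_subjects, n_parcels = 32L, frames_per_run = 100L,
    seed = seed, ...
  ))
}

# neural features + behavioral table sharing one latent factor (strength `link`)
make_cv_features <- function(n, link = 1, seed = 1) {
  withr::with_seed(seed, {
    g <- rnorm(n)
    ids <- sprintf("S%03d", seq_len(n))
    xf <- outer(g, rnorm(8)) + matrix(rnorm(n * 8, 0, 0.5), n)
    features <- tibble::as_tibble(xf, .name_repair = "minimal")
    names(features) <- sprintf("f%02d_d%d", 1:8, rep(1:2, 4))
    features <- dplyr::bind_cols(tibble::tibble(subject_id = ids), features)

    xb <- link * outer(g, rnorm(10)) + matrix(rnorm(n * 10), n)
    behavior <- tibble::as_tibble(xb, .name_repair = "minimal")
    names(behavior) <- sprintf("v%02d", 1:10)
    behavior <- prepare_behavior(
      dplyr::bind_cols(tibble::tibble(subject_id = ids), behavior))

    covariates <- tibble::tibble(subject_id = ids,
                                 age = runif(n, 22, 36),
                                 sex = sample(c("F", "M"), n, TRUE))
    list(features = features, behavior = behavior, covariates = covariates)
  })
}
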