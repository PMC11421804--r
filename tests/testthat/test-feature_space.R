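hand_agg <- function() {
  grid <- tidyr::expand_grid(
    subject_id = c("A", "B"), day = 1:2,
    state = c("I+", "I-", "II+", "II-", "III")
  )
  grid$n_perm <- 1L; grid$n_present <- 1L
  withr::with_seed(61, {
    grid$fo <- runif(nrow(grid))
    grid$mean_dt <- runif(nrow(grid), 1, 5)
    grid$var_dt <- runif(nrow(grid))
  })
  grid
}

test_that("the feature matrix follows the 3 x 5 x 2 schema exactly", {
  agg <- hand_agg()
  fm <- build_feature_matrix(agg, cap_labels = c("I+", "I-", "II+", "II-", "III"))
  expect_equal(ncol(fm), 31L)  # subject_id + 30 features
  schema <- attr(fm, "schema")
  expect_equal(nrow(schema), 30L)

  # spot-check entries against the source rows
  expect_equal(fm[["fo_I+_d1"]][fm$subject_id == "A"],
               agg$fo[agg$subject_id == "A" & agg$day == 1 & agg$state == "I+"])
  expect_equal(fm[["var_dt_III_d2"]][fm$subject_id == "B"],
               agg$var_dt[agg$subject_id == "B" & agg$day == 2 &
                            agg$state == "III"])
})

test_that("subjects never showing a CAP get zero columns, not NA", {
  agg <- hand_agg()
  agg <- agg[agg$state != "III", ]
  fm <- build_feature_matrix(agg, cap_labels = c("I+", "I-", "II+", "II-", "III"))
  expect_true(all(fm[["fo_III_d1"]] == 0))
  expect_true(all(fm[["mean_dt_III_d2"]] == 0))
  expect_false(anyNA(fm))
})

test_that("a missing day is an error naming the subjects", {
  agg <- hand_agg()
  agg <- agg[!(agg$subject_id == "B" & agg$day == 2), ]
  expect_error(build_feature_matrix(agg), "B")
})

make_blob_features <- function(centers, n_per, sd = 0.3, seed = 62) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      sweep(matrix(rnorm(n_per * ncol(centers), 0, sd), n_per), 2,
            centers[i, ], "+")
    }))
    fm <- tibble::as_tibble(x, .name_repair = "minimal")
    names(fm) <- sprintf("f%02d_d%d", seq_len(ncol(x)),
                         rep(1:2, length.out = ncol(x)))
    dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("S%03d", seq_len(nrow(x)))), fm)
  })
}

test_that("well-separated blobs are recovered exactly at the 70% cut", {
  centers <- matrix(c(0, 0, 0, 0, 8, 8, 8, 8, -8, 8, -8, 8), 3, 4, byrow = TRUE)
  fm <- make_blob_features(centers, n_per = 10)
  sg <- cluster_subgroups(fm, standardize = FALSE)
  expect_equal(length(sg$sizes), 3L)
  expect_equal(sg$sizes, c(10L, 10L, 10L))
  truth <- rep(1:3, each = 10)
  # perfect agreement up to label permutation
  tab <- table(truth, sg$assignments$subgroup)
  expect_equal(sum(apply(tab, 1, max)), 30L)
})

test_that("identical subjects collapse to one cluster with a warning", {
  fm <- make_blob_features(matrix(0, 1, 4), n_per = 12, sd = 0)
  expect_warning(sg <- cluster_subgroups(fm, standardize = FALSE), "single")
  expect_equal(length(sg$sizes), 1L)
  expect_equal(sg$sizes, 12L)
})

test_that("neural PCA recovers planted orthogonal factors", {
  withr::local_seed(63)
  n <- 60
  s1 <- rnorm(n); s2 <- rnorm(n)
  l1 <- c(rep(1, 5), rep(0, 5)); l2 <- c(rep(0, 5), rep(1, 5))
  x <- outer(s1, l1) + outer(s2, l2) + matrix(rnorm(n * 10, 0, 0.05), n)
  fm <- tibble::as_tibble(x, .name_repair = "minimal")
  names(fm) <- sprintf("f%02d_d%d", 1:10, rep(1:2, 5))
  fm <- dplyr::bind_cols(tibble::tibble(subject_id = sprintf("S%02d", 1:n)), fm)

  pca <- neural_pca(fm, n_components = 2, standardize = FALSE)
  # each planted loading vector is recovered by one of the two components
  r <- abs(cor(cbind(l1, l2), pca$loadings))
  expect_true(all(apply(r, 1, max) >= 0.95))
  expect_true(all(diff(pca$var_explained_all) <= 1e-8))
})

test_that("day-duplicated features give between-day loading r = 1", {
  withr::local_seed(64)
  n <- 40
  base <- matrix(rnorm(n * 6), n)
  x <- cbind(base, base)  # day 2 copies day 1
  fm <- tibble::as_tibble(x, .name_repair = "minimal")
  names(fm) <- c(sprintf("f%02d_d1", 1:6), sprintf("f%02d_d2", 1:6))
  fm <- dplyr::bind_cols(tibble::tibble(subject_id = sprintf("S%02d", 1:n)), fm)
  pca <- neural_pca(fm, n_components = 3, standardize = FALSE)
  expect_true(all(pca$day_loading_r$r > 1 - 1e-8))
})

test_that("a day-antisymmetric factor shows up as a day-flip component", {
  withr::local_seed(65)
  n <- 80
  s_trait <- rnorm(n, sd = 2)   # strong day-consistent factor
  s_state <- rnorm(n)           # day-flip factor
  l <- rnorm(6)
  day1 <- outer(s_trait, l) + outer(s_state, l)
  day2 <- outer(s_trait, l) - outer(s_state, l)
  x <- cbind(day1, day2) + matrix(rnorm(n * 12, 0, 0.05), n)
  fm <- tibble::as_tibble(x, .name_repair = "minimal")
  names(fm) <- c(sprintf("f%02d_d1", 1:6), sprintf("f%02d_d2", 1:6))
  fm <- dplyr::bind_cols(tibble::tibble(subject_id = sprintf("S%02d", 1:n)), fm)
  pca <- neural_pca(fm, n_components = 2, standardize = FALSE)
  expect_gt(max(pca$day_loading_r$r), 0.9)
  expect_lt(min(pca$day_loading_r$r), -0.9)
})

test_that("PCA reconstruction and sign conventions are deterministic", {
  withr::local_seed(66)
  x <- matrix(rnorm(30 * 8), 30)
  fm <- tibble::as_tibble(x, .name_repair = "minimal")
  names(fm) <- sprintf("f%02d_d%d", 1:8, rep(1:2, 4))
  fm <- dplyr::bind_cols(tibble::tibble(subject_id = sprintf("S%02d", 1:30)), fm)
  pca <- neural_pca(fm, n_components = 8, standardize = FALSE)
  recon <- as.matrix(pca$scores[, -1]) %*% t(pca$loadings)
  centered <- scale(x, center = TRUE, scale = FALSE)
  expect_lt(max(abs(recon - centered)), 1e-8)

  # largest-|loading| element of every component is positive
  for (j in seq_len(ncol(pca$loadings))) {
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
  }
  # subject order does not change the variance profile
  pca2 <- neural_pca(fm[rev(seq_len(30)), ], n_components = 8,
                     standardize = FALSE)
  expect_equal(pca$var_explained, pca2$var_explained, tolerance = 1e-8)
})

test_that("subgroup recovery works on a planted mixed cohort's true metrics", {
  # moderate idiosyncratic trait spread, so the planted subgroup structure
  # (presence of state III) dominates the feature geometry
  sim <- generate_cohort(sim_config(n_subjects = 30L, n_parcels = 16L,
                                    frames_per_run = 250L, trait_sd = 0.4,
                                    seed = 67))
  gt <- sim$ground_truth
  rows <- purrr::map_dfr(sim$cohort$subjects$subject_id, function(id) {
    purrr::map_dfr(1:2, function(d) {
      m <- compute_metrics(gt$state_sequences[[paste(id, d, sep = ".")]], 1:5)
      m$subject_id <- id; m$day <- d
      m
    })
  })
  rows$state <- gt$state_labels[rows$state]
  fm <- build_feature_matrix(rows, cap_labels = gt$state_labels)
  sg <- cluster_subgroups(fm)
  merged <- dplyr::inner_join(
    sg$assignments,
    tibble::tibble(subject_id = names(gt$subgroup), truth = unname(gt$subgroup)),
    by = "subject_id"
  )
  # subgroup C (possessing state III) is enriched in one recovered cluster
  tab <- table(merged$truth == "C", merged$subgroup)
  best <- which.max(tab["TRUE", ])
  p <- stats::fisher.test(merged$truth == "C",
                          merged$subgroup == colnames(tab)[best])$p.value
  expect_lt(p, 0.05)
})
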