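toy_behavior <- function(n = 30, p = 8, seed = 71, rt_cols = integer()) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n)
    x[, rt_cols] <- exp(x[, rt_cols, drop = FALSE])  # positive RT-like
    tab <- tibble::as_tibble(x, .name_repair = "minimal")
    names(tab) <- sprintf("v%02d", seq_len(p))
    tab <- dplyr::bind_cols(tibble::tibble(subject_id = sprintf("S%02d", 1:n)),
                            tab)
    meta <- tibble::tibble(variable = sprintf("v%02d", seq_len(p)),
                           is_rt = seq_len(p) %in% rt_cols)
    list(table = tab, meta = meta)
  })
}

test_that("behavioral preparation applies 1/RT then standardizes", {
  tab <- tibble::tibble(subject_id = c("a", "b"), rt = c(2, 4), other = c(1, 3))
  meta <- tibble::tibble(variable = c("rt", "other"), is_rt = c(TRUE, FALSE))
  prep <- prepare_behavior(tab, meta)
  # the reciprocal [0.5, 0.25] standardizes to (+1/sqrt(2), -1/sqrt(2))
  expect_equal(prep$rt, as.numeric(scale(c(0.5, 0.25))))
  # every column centered and unit-scaled
  for (v in c("rt", "other")) {
    expect_lt(abs(mean(prep[[v]])), 1e-12)
    expect_equal(sd(prep[[v]]), 1, tolerance = 1e-12)
  }
  # provenance guard blocks double preparation
  expect_error(prepare_behavior(prep, meta), "already prepared")
})

test_that("preparation rejects bad inputs explicitly", {
  tab <- tibble::tibble(subject_id = c("a", "b"), rt = c(2, -1))
  meta <- tibble::tibble(variable = "rt", is_rt = TRUE)
  expect_error(prepare_behavior(tab, meta), "non-positive.*subject b")

  tab2 <- tibble::tibble(subject_id = c("a", "b"), flat = c(1, 1), v = c(1, 2))
  expect_error(prepare_behavior(tab2), "constant")
})

test_that("the PCA permutation test flags planted structure at minimal p", {
  withr::local_seed(72)
  n <- 40; p <- 10
  f <- rnorm(n)
  x <- outer(f, rnorm(p)) * 3 + matrix(rnorm(n * p, 0, 0.5), n)
  tab <- tibble::as_tibble(x, .name_repair = "minimal")
  names(tab) <- sprintf("v%02d", 1:p)
  tab <- dplyr::bind_cols(tibble::tibble(subject_id = sprintf("S%02d", 1:n)), tab)
  prep <- prepare_behavior(tab)

  res <- pca_permutation_test(prep, n_perm = 199, seed = 5)
  expect_equal(res$results$p[1], 1 / 200)
  expect_true(res$results$significant[1])
  # add-one p-values live in (0, 1]
  expect_true(all(res$results$p > 0 & res$results$p <= 1))

  # deterministic under the same seed
  res2 <- pca_permutation_test(prep, n_perm = 199, seed = 5)
  expect_identical(res$results$p, res2$results$p)
})

test_that("split-half PC geometry is reproducible only when structure exists", {
  withr::local_seed(73)
  n <- 60; p <- 12
  f <- rnorm(n)
  strong <- outer(f, rnorm(p)) * 4 + matrix(rnorm(n * p, 0, 0.4), n)
  tabs <- lapply(list(strong, matrix(rnorm(n * p), n)), function(x) {
    tab <- tibble::as_tibble(x, .name_repair = "minimal")
    names(tab) <- sprintf("v%02d", 1:p)
    prepare_behavior(
      dplyr::bind_cols(tibble::tibble(subject_id = sprintf("S%02d", 1:n)), tab))
  })
  rep_strong <- splithalf_reproducibility(tabs[[1]], n_perm = 40, seed = 6)
  rep_noise <- splithalf_reproducibility(tabs[[2]], n_perm = 40, seed = 6)
  expect_gt(rep_strong$summary$mean_r[1], 0.9)
  expect_lt(rep_noise$summary$mean_r[1], rep_strong$summary$mean_r[1])
})

test_that("association fitting recovers planted coefficients and is exact in the limit", {
  withr::local_seed(74)
  n <- 300
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- rnorm(n)
  age <- runif(n, 22, 36); sex <- sample(c("F", "M"), n, TRUE)
  y <- 0.5 * x1 + rnorm(n, 0, 0.1)
  dat <- tibble::tibble(y = y, x1 = x1, x2 = x2, x3 = x3, age = age, sex = sex)
  fit <- fit_association(dat, "y", c("x1", "x2", "x3"), c("age", "sex"))
  td <- tidy(fit)
  b1 <- td[td$term == "x1", ]
  expect_lt(abs(b1$estimate - 0.5), 3 * b1$std_error)
  expect_true(all(td$partial_r2[td$term %in% c("x2", "x3")] < 0.02))
  expect_true(all(td$partial_r2 >= 0 & td$partial_r2 <= 1))

  # perfect fit: y = x1 exactly
  dat2 <- dat; dat2$y <- dat2$x1
  fit2 <- suppressWarnings(fit_association(dat2, "y", c("x1", "x2"), "age"))
  expect_equal(tidy(fit2)$partial_r2[1], 1, tolerance = 1e-10)
  expect_equal(glance(fit2)$r_squared, 1, tolerance = 1e-10)
})

test_that("partial R2 equals the squared partial correlation oracle", {
  withr::local_seed(75)
  for (i in 1:20) {
    n <- 80
    dat <- tibble::tibble(y = rnorm(n), x1 = rnorm(n), x2 = rnorm(n),
                          x3 = rnorm(n))
    fit <- fit_association(dat, "y", c("x1", "x2", "x3"))
    td <- tidy(fit)
    for (v in c("x1", "x2", "x3")) {
      others <- setdiff(c("x1", "x2", "x3"), v)
      ry <- stats::residuals(lm(stats::reformulate(others, "y"), dat))
      rv <- stats::residuals(lm(stats::reformulate(others, v), dat))
      expect_lt(abs(td$partial_r2[td$term == v] - cor(ry, rv)^2), 1e-10)
    }
  }
})

test_that("collinear predictors are rejected", {
  withr::local_seed(76)
  n <- 60
  x1 <- rnorm(n)
  dat <- tibble::tibble(y = rnorm(n), x1 = x1, x2 = 2 * x1, x3 = rnorm(n))
  expect_error(fit_association(dat, "y", c("x1", "x2", "x3")), "collinear")
})

test_that("cross-validated prediction beats its null only under a planted link", {
  withr::local_seed(77)
  n <- 60
  fm <- make_cv_features(n, link = 1.5, seed = 78)
  res <- crossval_predict(fm$features, fm$behavior, fm$covariates,
                          n_perm = 30, n_neural = 2, seed = 9)
  expect_gt(res$summary$r2_mean, res$summary$null_mean)
  expect_lt(res$summary$p_vs_null, 0.05)

  fm0 <- make_cv_features(n, link = 0, seed = 79)
  res0 <- crossval_predict(fm0$features, fm0$behavior, fm0$covariates,
                           n_perm = 30, n_neural = 2, seed = 9)
  expect_gt(res0$summary$p_vs_null, 0.05)

  # deterministic under seed
  res_b <- crossval_predict(fm$features, fm$behavior, fm$covariates,
                            n_perm = 30, n_neural = 2, seed = 9)
  expect_identical(res$draws, res_b$draws)
})

test_that("subgroup t-tests do the bookkeeping the correction requires", {
  withr::local_seed(80)
  n <- 30
  scores <- tibble::tibble(subject_id = sprintf("S%02d", 1:n))
  for (j in 1:15) scores[[paste0("bpc", j)]] <- rnorm(n)
  sg <- tibble::tibble(subject_id = scores$subject_id,
                       subgroup = rep(1:3, each = 10))
  tt <- subgroup_ttests(scores, sg)
  expect_equal(unique(tt$family_size), 45L)  # 3 pairs x 15 components
  expect_equal(nrow(tt), 45L)
  expect_true(all(tt$p_bonferroni >= tt$p, na.rm = TRUE))

  # planted shift of 1 SD at n = 100 per group is essentially always detected
  big <- tibble::tibble(subject_id = sprintf("T%03d", 1:200),
                        s = c(rnorm(100), rnorm(100, 1)))
  sg2 <- tibble::tibble(subject_id = big$subject_id,
                        subgroup = rep(1:2, each = 100))
  tt2 <- subgroup_ttests(big, sg2, components = "s")
  expect_lt(tt2$p, 0.001)
})
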