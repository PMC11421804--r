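# build a toy ledger whose capsets are noisy copies of planted patterns
toy_ledger <- function(patterns, h = 10, noise = 0.01, k_hat = NULL, seed = 1) {
  k <- nrow(patterns)
  rows <- withr::with_seed(seed, purrr::map(seq_len(h), function(p) {
    shuffle <- sample(k)
    cents <- patterns[shuffle, , drop = FALSE] +
      matrix(rnorm(k * ncol(patterns), 0, noise), k)
    tibble::tibble(
      perm = p, split = 1L, members = list(character()),
      k_hat = k_hat %||% k, k_method = "knee",
      silhouettes = list(NULL),
      capset = list(capdyn:::new_capset(cents, rep(10L, k), 0)),
      metrics = list(NULL), ok = TRUE, error = NA_character_
    )
  }))
  dplyr::bind_rows(rows)
}

z_rows <- function(m) t(apply(m, 1, function(v) (v - mean(v)) / sd(v)))

test_that("basis construction aggregates, averages and z-scores", {
  withr::local_seed(31)
  pats <- matrix(rnorm(3 * 40), 3, 40)
  led <- toy_ledger(pats, h = 8, noise = 1e-6)
  basis <- build_basis_set(led, 3)
  expect_s3_class(basis, "cap_basis")
  expect_equal(basis$k, 3L)
  expect_equal(basis$n_contributing, 8L)
  expect_equal(basis$cluster_sizes, rep(8L, 3))

  # patterns are z-scored across parcels
  expect_lt(max(abs(rowMeans(basis$patterns))), 1e-8)
  expect_lt(max(abs(apply(basis$patterns, 1, sd) - 1)), 1e-8)

  # and equal the z-scored planted patterns up to row order
  target <- z_rows(pats)
  r <- cor(t(basis$patterns), t(target))
  expect_true(all(apply(r, 2, max) > 1 - 1e-6))
})

test_that("noisy centroid copies still aggregate to the planted patterns", {
  withr::local_seed(32)
  pats <- matrix(rnorm(4 * 60), 4, 60)
  led <- toy_ledger(pats, h = 20, noise = 0.3)
  basis <- build_basis_set(led, 4)
  r <- cor(t(basis$patterns), t(z_rows(pats)))
  expect_true(all(apply(r, 2, max) >= 0.99))
})

test_that("basis construction is invariant to ledger row order", {
  withr::local_seed(33)
  pats <- matrix(rnorm(3 * 30), 3, 30)
  led <- toy_ledger(pats, h = 12, noise = 0.1)
  b1 <- build_basis_set(led, 3)
  b2 <- build_basis_set(led[sample(nrow(led)), ], 3)
  r <- cor(t(b1$patterns), t(b2$patterns))
  expect_true(all(apply(r, 1, max) > 1 - 1e-12))
})

test_that("basis construction demands enough qualifying permutations", {
  withr::local_seed(34)
  pats <- matrix(rnorm(3 * 30), 3, 30)
  led <- toy_ledger(pats, h = 5)
  expect_error(build_basis_set(led, 4), ">= 2 permutation entries")
})

test_that("matching is one-to-one with identity and sign-flip structure", {
  withr::local_seed(35)
  pats <- z_rows(matrix(rnorm(4 * 50), 4, 50))
  basis <- structure(list(patterns = pats, labels = paste0("C", 1:4), k = 4L),
                     class = "cap_basis")
  est <- capdyn:::new_capset(pats, rep(1L, 4), 0)
  m <- match_caps(est, basis)
  expect_equal(m$labels, paste0("C", 1:4))
  expect_equal(unname(diag(m$r_matrix)), rep(1, 4), tolerance = 1e-8)

  # sign-flipped anti-correlated pair: the flipped pattern matches its partner
  pair <- rbind(pats[1, ], -pats[1, ], pats[3, ], pats[4, ])
  basis2 <- structure(list(patterns = pair, labels = c("I+", "I-", "A", "B"),
                           k = 4L), class = "cap_basis")
  est2 <- capdyn:::new_capset(rbind(-pats[1, ], pats[3, ]), rep(1L, 2), 0)
  m2 <- match_caps(est2, basis2)
  expect_equal(m2$labels[1], "I-")
  expect_equal(unname(m2$r_matrix[1, "I-"]), 1, tolerance = 1e-8)
  expect_equal(unname(m2$r_matrix[1, "I+"]), -1, tolerance = 1e-8)
})

test_that("a 4-CAP solution against a 5-CAP basis leaves the extra unmatched", {
  withr::local_seed(36)
  pats <- z_rows(matrix(rnorm(5 * 50), 5, 50))
  basis <- structure(list(patterns = pats,
                          labels = c("I+", "I-", "II+", "II-", "III"), k = 5L),
                     class = "cap_basis")
  est <- capdyn:::new_capset(pats[1:4, ] + matrix(rnorm(200, 0, 0.05), 4),
                             rep(1L, 4), 0)
  m <- match_caps(est, basis)
  expect_setequal(m$labels, c("I+", "I-", "II+", "II-"))
  expect_false("III" %in% m$labels)
})

test_that("greedy matching agrees with the exhaustive optimum almost always", {
  # estimated CAPs are noisy, shuffled copies of basis CAPs at noise levels
  # up to the point where identities blur; the greedy order is stressed by
  # the cross-correlations the anti-correlated structure induces
  withr::local_seed(37)
  agree <- 0L
  n_trials <- 200L
  for (i in seq_len(n_trials)) {
    ke <- sample(3:4, 1)
    kb <- sample(ke:5, 1)
    noise <- runif(1, 0.2, 0.8)
    base <- matrix(rnorm(kb * 40), kb, 40)
    base[2, ] <- -base[1, ]  # an anti-correlated pair among the basis CAPs
    basis <- structure(list(patterns = base,
                            labels = paste0("C", seq_len(kb)), k = kb),
                       class = "cap_basis")
    est <- capdyn:::new_capset(
      base[sample(kb, ke), , drop = FALSE] +
        matrix(rnorm(ke * 40, 0, noise), ke), rep(1L, ke), 0)
    m <- match_caps(est, basis)
    got <- sum(m$r_matrix[cbind(seq_len(ke), m$assignment$basis)])
    opt <- exhaustive_match(m$r_matrix)
    if (got >= opt$total - 1e-12) agree <- agree + 1L
  }
  expect_gte(agree / n_trials, 0.95)
})

test_that("package matching equals the exhaustive optimum on structured inputs", {
  # on near-orthogonal patterns (the realistic regime) greedy is optimal
  withr::local_seed(38)
  ok <- 0L
  for (i in 1:50) {
    pats <- z_rows(matrix(rnorm(4 * 80), 4, 80))
    basis <- structure(list(patterns = pats, labels = paste0("C", 1:4), k = 4L),
                       class = "cap_basis")
    est <- capdyn:::new_capset(
      pats[sample(4), ] + matrix(rnorm(320, 0, 0.4), 4), rep(1L, 4), 0)
    m <- match_caps(est, basis)
    r <- m$r_matrix
    opt <- exhaustive_match(r)
    got <- sum(r[cbind(1:4, match(m$labels, basis$labels))])
    if (got >= opt$total - 1e-12) ok <- ok + 1L
  }
  expect_gte(ok / 50, 0.95)
})

test_that("occurrence statistics count per split and z-score across subjects", {
  # single permutation: a subject in a split with k_hat = 5
  led <- tibble::tibble(
    perm = c(1L, 1L), split = c(1L, 2L),
    members = list(c("a", "b"), c("c", "d")),
    k_hat = c(5L, 4L), k_method = "knee",
    silhouettes = list(NULL), capset = list(NULL), metrics = list(NULL),
    ok = TRUE, error = NA_character_
  )
  occ <- occurrence_stats(led, c(4L, 5L))
  a <- occ[occ$subject_id == "a", ]
  expect_equal(a$occ5_s1, 1L)
  expect_equal(a$occ4_s1, 0L)
  expect_equal(a$delta_s1, 1L)
  c_ <- occ[occ$subject_id == "c", ]
  expect_equal(c_$delta_s2, -1L)

  # delta_z standardized when defined
  expect_lt(abs(mean(occ$delta_z)), 1e-8)
  expect_lt(abs(sd(occ$delta_z) - 1), 1e-8)
})

test_that("constant k across splits gives zero delta_z with a warning", {
  led <- tibble::tibble(
    perm = c(1L, 1L, 2L, 2L), split = c(1L, 2L, 1L, 2L),
    members = list(c("a", "b"), c("c", "d"), c("a", "c"), c("b", "d")),
    k_hat = 4L, k_method = "knee",
    silhouettes = list(NULL), capset = list(NULL), metrics = list(NULL),
    ok = TRUE, error = NA_character_
  )
  expect_warning(occ <- occurrence_stats(led, c(4L, 5L)), "constant")
  expect_true(all(occ$delta_z == 0))
})
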