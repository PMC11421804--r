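#' Preprocess a behavioral table
#'
#' Replaces reaction-time-flagged variables by their reciprocals (so larger
#' always means better performance), then centers and unit-scales every
#' column. A provenance attribute guards against accidental double
#' transformation. Columns that are constant after preprocessing are an
#' error: they carry no behavioral signal and break downstream PCA.
#'
#' @param table Tibble, `subject_id` plus numeric behavioral columns.
#' @param meta Tibble with `variable` and logical `is_rt` (others optional).
#'
#' @return The prepared tibble with attribute `prepared = TRUE`.
#' @export
prepare_behavior <- function(table, meta = NULL) {
  if (isTRUE(attr(table, "prepared"))) {
    abort("table is already prepared (1/RT + scaling must not be applied twice)")
  }
  vars <- setdiff(names(table), "subject_id")
  rt_vars <- if (is.null(meta)) character() else meta$variable[meta$is_rt]
  out <- table
  for (v in intersect(rt_vars, vars)) {
    bad <- which(out[[v]] <= 0)
    if (length(bad)) {
      abort(sprintf("RT variable %s is non-positive for subject %s",
                    v, out$subject_id[bad[1]]))
    }
    out[[v]] <- 1 / out[[v]]
  }
  const <- vars[vapply(vars, function(v) sd(out[[v]]) == 0, TRUE)]
  if (length(const)) {
    abort(sprintf("constant behavioral column(s) after preprocessing: %s",
                  paste(const, collapse = ", ")))
  }
  for (v in vars) out[[v]] <- as.numeric(scale(out[[v]]))
  attr(out, "prepared") <- TRUE
  out
}

behavior_values <- function(table) {
  x <- as.matrix(table[setdiff(names(table), "subject_id")])
  rownames(x) <- table$subject_id
  x
}

#' Permutation significance of behavioral principal components
#'
#' PCA of the prepared table, with per-component significance against a null
#' in which subject order is shuffled independently within every variable —
#' breaking the inter-variable correlation structure while preserving each
#' variable's marginal distribution. p-values use the add-one estimator
#' `p = (1 + #(null >= observed)) / (1 + n_perm)` on the variance explained.
#'
#' @param table Prepared behavioral tibble (see [prepare_behavior()]).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Seed.
#' @param alpha Flagging level (default 0.05).
#'
#' @return A `cap_pca_test`: list with `pca` (a `cap_pca`-like list),
#'   `results` (tibble `component`, `var_explained`, `p`, `significant`),
#'   `n_significant`, `alpha`, `n_perm`.
#' @export
pca_permutation_test <- function(table, n_perm = 1000L, seed = NULL,
                                 alpha = 0.05) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) warn("n_perm < 100 gives coarse p-value resolution")
  x <- behavior_values(table)
  obs <- prcomp(x, center = TRUE, scale. = FALSE)
  obs_ve <- obs$sdev^2 / sum(obs$sdev^2)
  n_comp <- length(obs_ve)

  seeds <- derive_seeds(seed %||% 1L, n_perm)
  exceed <- numeric(n_comp)
  for (b in seq_len(n_perm)) {
    xb <- with_seed_(seeds[b], apply(x, 2L, sample))
    sv <- prcomp(xb, center = TRUE, scale. = FALSE)$sdev^2
    ve_b <- sv / sum(sv)
    if (length(ve_b) < n_comp) ve_b <- c(ve_b, rep(0, n_comp - length(ve_b)))
    exceed <- exceed + (ve_b[seq_len(n_comp)] >= obs_ve)
  }
  p <- (1 + exceed) / (1 + n_perm)
  results <- tibble::tibble(component = seq_len(n_comp),
                            var_explained = 100 * obs_ve,
                            p = p, significant = p < alpha)
  structure(list(pca = fix_pca_signs(obs), results = results,
                 n_significant = sum(results$significant),
                 alpha = alpha, n_perm = n_perm),
            class = "cap_pca_test")
}

#' @export
print.cap_pca_test <- function(x, ...) {
  cat(sprintf("<cap_pca_test> %d/%d components significant at p < %g (%d permutations)\n",
              x$n_significant, nrow(x$results), x$alpha, x$n_perm))
  invisible(x)
}

#' Split-half reproducibility of PC geometry
#'
#' Per permutation, subjects are split into two halves, PCA is fit in each
#' half, and the absolute Pearson correlation between the rank-matched
#' loading vectors is recorded (the absolute value absorbs the sign
#' indeterminacy of principal axes).
#'
#' @param table Prepared behavioral tibble.
#' @param n_perm Number of split-half permutations.
#' @param n_components Components to track.
#' @param seed Seed.
#'
#' @return List with `draws` (tibble `perm`, `component`, `similarity`) and
#'   `summary` (tibble `component`, `mean_r`, `sd_r`).
#' @export
splithalf_reproducibility <- function(table, n_perm = 100L, n_components = 3L,
                                      seed = NULL) {
  x <- behavior_values(table)
  if (nrow(x) < 8L) abort("need >= 8 subjects")
  n_components <- min(n_components, ncol(x), nrow(x) %/% 2L - 1L)
  seeds <- derive_seeds(seed %||% 1L, n_perm)
  draws <- purrr::map_dfr(seq_len(n_perm), function(b) {
    halves <- split_half(rownames(x), seeds[b])
    l1 <- prcomp(x[halves$split1, ], center = TRUE, scale. = FALSE)$rotation
    l2 <- prcomp(x[halves$split2, ], center = TRUE, scale. = FALSE)$rotation
    nc <- min(n_components, ncol(l1), ncol(l2))
    tibble::tibble(
      perm = b, component = seq_len(nc),
      similarity = vapply(seq_len(nc),
                          function(j) abs(cor(l1[, j], l2[, j])), 1)
    )
  })
  summary <- dplyr::group_by(draws, .data$component) |>
    dplyr::summarise(mean_r = mean(.data$similarity),
                     sd_r = sd(.data$similarity), .groups = "drop")
  list(draws = draws, summary = summary)
}

#' Neuro-behavioral multiple regression with partial R-squared
#'
#' Ordinary least squares of one behavioral component score on the neural
#' component scores plus covariates (the canonical model is
#' `behavioral PC1 ~ neural PC1 + PC2 + PC3 + age + sex`). For every
#' predictor, the coefficient of partial determination is reported:
#' `partial R2 = (SSE_without - SSE_full) / SSE_without`, the proportional
#' reduction in residual sum of squares when the predictor enters the model.
#'
#' @param data Tibble containing the response and all predictor columns.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor columns of interest.
#' @param covariates Character vector of nuisance columns (default none).
#' @param bonferroni_family Family size for Bonferroni correction of the
#'   predictor p-values (default: number of predictors of interest).
#' @param condition_threshold Error when the model-matrix condition number
#'   exceeds this (default 1e8), signalling collinear predictors.
#'
#' @return A `cap_assoc`: list with `terms` (per-predictor tibble), `model_fit`
#'   (one-row tibble with R2, adj. R2, F, df, p) and the underlying `lm`.
#' @export
fit_association <- function(data, response, predictors, covariates = character(),
                            bonferroni_family = NULL,
                            condition_threshold = 1e8) {
  all_pred <- c(predictors, covariates)
  if (nrow(data) < length(all_pred) + 10L) {
    abort("need at least 10 more subjects than predictors")
  }
  data <- data[stats::complete.cases(data[c(response, all_pred)]), ]
  fml <- stats::reformulate(all_pred, response = response)
  fit <- lm(fml, data = data)
  mm <- stats::model.matrix(fit)
  if (kappa(mm, exact = TRUE) > condition_threshold) {
    abort("collinear predictors: model matrix condition number too large")
  }
  sse_full <- sum(stats::residuals(fit)^2)
  sm <- summary(fit)

  coefs <- sm$coefficients
  term_rows <- purrr::map_dfr(all_pred, function(v) {
    reduced <- lm(stats::reformulate(setdiff(all_pred, v), response = response),
                  data = data)
    sse_red <- sum(stats::residuals(reduced)^2)
    partial <- if (sse_red > 0) (sse_red - sse_full) / sse_red else 0
    # factor predictors (e.g. sex) expand to one dummy column here
    row_name <- grep(paste0("^", v), rownames(coefs), value = TRUE)[1]
    tibble::tibble(
      term = v,
      estimate = coefs[row_name, "Estimate"],
      std_error = coefs[row_name, "Std. Error"],
      statistic = coefs[row_name, "t value"],
      p_value = coefs[row_name, "Pr(>|t|)"],
      partial_r2 = partial,
      role = if (v %in% predictors) "predictor" else "covariate"
    )
  })
  family <- bonferroni_family %||% length(predictors)
  term_rows$p_bonferroni <- pmin(1, term_rows$p_value * family)

  f <- sm$fstatistic
  model_fit <- tibble::tibble(
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    statistic = unname(f[1]), df = unname(f[2]), df_residual = unname(f[3]),
    p_value = pf(f[1], f[2], f[3], lower.tail = FALSE),
    n = nrow(data), bonferroni_family = family
  )
  structure(list(terms = term_rows, model_fit = model_fit, model = fit),
            class = "cap_assoc")
}

#' @export
print.cap_assoc <- function(x, ...) {
  g <- x$model_fit
  cat(sprintf("<cap_assoc> R2 = %.3f (adj. %.3f), F(%g, %g) = %.3f, p = %.3g\n",
              g$r_squared, g$adj_r_squared, g$df, g$df_residual,
              g$statistic, g$p_value))
  print(x$terms)
  invisible(x)
}

#' Split-half cross-validated prediction of behavioral scores
#'
#' Per permutation: subjects split in half; neural PCA and behavioral PCA
#' are refit on split 1 only; the association model (behavioral component ~
#' neural components + covariates) is estimated on split 1; split-2 subjects
#' are projected onto the split-1 component spaces (split-1 centering and
#' scaling); and held-out performance is `R2 = 1 - SSE / SST` on split 2. A
#' null draw shuffles split-2 behavioral scores before scoring.
#'
#' @param features Neural feature tibble ([build_feature_matrix()]).
#' @param behavior Prepared behavioral tibble.
#' @param covariates Tibble with `subject_id` and covariate columns.
#' @param n_perm Number of split-half permutations.
#' @param n_neural Number of neural components used as predictors.
#' @param behavioral_component Which behavioral PC is predicted (default 1).
#' @param covariate_names Covariate columns to include (default age + sex).
#' @param seed Seed.
#'
#' @return List with `draws` (tibble `perm`, `r2`, `r2_null`) and `summary`
#'   (one-row tibble with means, SDs, and the add-one permutation p-value
#'   for mean observed R2 against the null draws).
#' @export
crossval_predict <- function(features, behavior, covariates,
                             n_perm = 100L, n_neural = 3L,
                             behavioral_component = 1L,
                             covariate_names = c("age", "sex"),
                             seed = NULL) {
  ids <- intersect(features$subject_id, behavior$subject_id)
  if (length(ids) < 20L) abort("need >= 20 subjects with both feature sets")
  xf <- feature_values(features[match(ids, features$subject_id), ])
  xb <- behavior_values(behavior[match(ids, behavior$subject_id), ])
  cov <- covariates[match(ids, covariates$subject_id), , drop = FALSE]
  seeds <- derive_seeds(seed %||% 1L, n_perm)

  project <- function(x_new, pc, j) {
    xs <- sweep(x_new, 2L, pc$center, "-")
    if (!isFALSE(pc$scale[1])) xs <- sweep(xs, 2L, pc$scale, "/")
    xs %*% pc$rotation[, j, drop = FALSE]
  }

  draws <- purrr::map_dfr(seq_len(n_perm), function(b) {
    ss <- derive_seeds(seeds[b], 2L)
    halves <- split_half(ids, ss[1])
    i1 <- match(halves$split1, ids); i2 <- match(halves$split2, ids)
    keep <- apply(xf[i1, , drop = FALSE], 2L, sd) > 0
    pc_n <- prcomp(xf[i1, keep, drop = FALSE], center = TRUE, scale. = TRUE)
    pc_b <- prcomp(xb[i1, , drop = FALSE], center = TRUE, scale. = FALSE)
    nn <- min(n_neural, ncol(pc_n$rotation))
    if (ncol(pc_b$rotation) < behavioral_component) {
      return(tibble::tibble(perm = b, r2 = NA_real_, r2_null = NA_real_))
    }
    train <- data.frame(
      y = pc_b$x[, behavioral_component],
      pc_n$x[, seq_len(nn), drop = FALSE]
    )
    names(train)[-1] <- paste0("npc", seq_len(nn))
    train <- cbind(train, cov[i1, covariate_names, drop = FALSE])
    fit <- lm(y ~ ., data = train)

    test <- data.frame(project(xf[i2, keep, drop = FALSE], pc_n, seq_len(nn)))
    names(test) <- paste0("npc", seq_len(nn))
    test <- cbind(test, cov[i2, covariate_names, drop = FALSE])
    y2 <- as.numeric(project(xb[i2, , drop = FALSE], pc_b, behavioral_component))
    pred <- stats::predict(fit, newdata = test)
    sst <- sum((y2 - mean(y2))^2)
    r2 <- 1 - sum((y2 - pred)^2) / sst
    y2_null <- with_seed_(ss[2], sample(y2))
    r2_null <- 1 - sum((y2_null - pred)^2) / sst
    tibble::tibble(perm = b, r2 = r2, r2_null = r2_null)
  })
  ok <- draws[stats::complete.cases(draws), ]
  p <- (1 + sum(ok$r2_null >= mean(ok$r2))) / (1 + nrow(ok))
  list(draws = draws,
       summary = tibble::tibble(
         n_perm = nrow(ok), r2_mean = mean(ok$r2), r2_sd = sd(ok$r2),
         null_mean = mean(ok$r2_null), null_sd = sd(ok$r2_null),
         p_vs_null = p
       ))
}

#' Subgroup comparisons of behavioral component scores
#'
#' Welch two-sample two-sided t-tests between every subgroup pair for each
#' behavioral component, Bonferroni-corrected over the full family
#' (components tested x subgroup pairs), with the family size recorded.
#'
#' @param scores Tibble: `subject_id` plus component score columns.
#' @param subgroups Tibble with `subject_id` and `subgroup`.
#' @param components Which score columns to test (default: all non-id).
#'
#' @return Tibble with `component`, `group1`, `group2`, group means, `t`,
#'   `df`, `p`, `p_bonferroni`, `family_size`.
#' @export
subgroup_ttests <- function(scores, subgroups, components = NULL) {
  components <- components %||% setdiff(names(scores), "subject_id")
  df <- dplyr::inner_join(scores, subgroups, by = "subject_id")
  groups <- sort(unique(df$subgroup))
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  family <- length(pairs) * length(components)
  out <- purrr::map_dfr(components, function(comp) {
    purrr::map_dfr(pairs, function(pr) {
      x <- df[[comp]][df$subgroup == pr[1]]
      y <- df[[comp]][df$subgroup == pr[2]]
      if (length(x) < 3L || length(y) < 3L) {
        abort("each compared subgroup needs >= 3 members")
      }
      if (sd(x) == 0 && sd(y) == 0) {
        warn(sprintf("degenerate variance comparing %s vs %s on %s",
                     pr[1], pr[2], comp))
        return(tibble::tibble(component = comp, group1 = pr[1], group2 = pr[2],
                              mean1 = mean(x), mean2 = mean(y),
                              t = NA_real_, df = NA_real_, p = NA_real_))
      }
      tt <- t.test(x, y)  # Welch, two-sided
      tibble::tibble(component = comp, group1 = pr[1], group2 = pr[2],
                     mean1 = mean(x), mean2 = mean(y),
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value)
    })
  })
  out$p_bonferroni <- pmin(1, out$p * family)
  out$family_size <- family
  out
}
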