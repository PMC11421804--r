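#' Tidy a neuro-behavioral association fit
#'
#' @param x A `cap_assoc` from [fit_association()].
#' @param ... Unused.
#' @return Tibble with one row per model term: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `partial_r2`, `p_bonferroni`, `role`.
#' @export
tidy.cap_assoc <- function(x, ...) x$terms

#' One-row model summary of an association fit
#'
#' @param x A `cap_assoc`.
#' @param ... Unused.
#' @return One-row tibble: R-squared, adjusted R-squared, F statistic with
#'   degrees of freedom, model p-value, n.
#' @export
glance.cap_assoc <- function(x, ...) x$model_fit

#' Tidy PCA loadings
#'
#' @param x A `cap_pca` from [neural_pca()].
#' @param ... Unused.
#' @return Long tibble: `feature`, `component`, `loading`.
#' @export
tidy.cap_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "component",
                        values_to = "loading")
}

#' One-row-per-component PCA summary
#'
#' @param x A `cap_pca`.
#' @param ... Unused.
#' @return Tibble: `component`, `var_explained` (%), `day_loading_r`.
#' @export
glance.cap_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$var_explained),
                 var_explained = x$var_explained,
                 day_loading_r = x$day_loading_r$r)
}

#' Tidy a behavioral PCA permutation test
#'
#' @param x A `cap_pca_test`.
#' @param ... Unused.
#' @return The per-component results tibble.
#' @export
tidy.cap_pca_test <- function(x, ...) x$results

#' Tidy subgroup assignments
#'
#' @param x A `cap_subgroups`.
#' @param ... Unused.
#' @return Tibble `subject_id`, `subgroup`.
#' @export
tidy.cap_subgroups <- function(x, ...) x$assignments
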