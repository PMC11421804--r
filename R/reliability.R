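#' ICC(2,1): two-way random effects, single measure, absolute agreement
#'
#' From the two-way random-effects ANOVA decomposition of a subjects x
#' sessions matrix (n subjects, k sessions):
#' `ICC(2,1) = (MSR - MSE) / (MSR + (k - 1) MSE + (k / n) (MSC - MSE))`,
#' where MSR, MSC and MSE are the between-subjects, between-sessions and
#' residual mean squares.
#'
#' @param scores Numeric subjects x sessions matrix, >= 2 rows and columns,
#'   all finite.
#'
#' @return The ICC value (a single number, at most 1).
#' @export
icc_2_1 <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2L || k < 2L) abort("need >= 2 subjects and >= 2 sessions")
  if (any(!is.finite(scores))) abort("`scores` must be finite")
  grand <- mean(scores)
  if (sum((scores - grand)^2) == 0) {
    abort("ICC undefined: zero total variance", class = "capdyn_icc_undefined")
  }
  row_m <- rowMeans(scores); col_m <- colMeans(scores)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((scores - grand)^2) - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom == 0) {
    abort("ICC undefined: zero denominator", class = "capdyn_icc_undefined")
  }
  (msr - mse) / denom
}

#' Day-to-day reliability of temporal metrics
#'
#' Pearson correlation (with two-sided p) across subjects between day-1 and
#' day-2 permutation-averaged values, per CAP and metric, plus ICC(2,1) of
#' the same subjects x days matrix. Subject pairs whose values are zero on
#' both days (a CAP structurally absent for that subject, e.g. CAP III in a
#' subject never producing a 5-CAP solution) are excluded.
#'
#' @param agg Aggregated metrics from [aggregate_metrics()] (ideally with
#'   `absent_as_zero = FALSE` for CAPs that can be absent).
#' @param metrics Which metric columns to assess.
#' @param drop_double_zero Exclude both-days-zero pairs (default `TRUE`).
#'
#' @return Tibble with `state`, `metric`, `n`, `r`, `p`, `icc21`.
#' @export
day_reliability <- function(agg, metrics = c("fo", "mean_dt", "var_dt"),
                            drop_double_zero = TRUE) {
  long <- tidyr::pivot_longer(agg, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  wide <- tidyr::pivot_wider(long,
                             id_cols = c("subject_id", "state", "metric"),
                             names_from = "day", values_from = "value",
                             names_prefix = "day")
  dplyr::group_by(wide, .data$state, .data$metric) |>
    dplyr::group_modify(function(df, key) {
      df <- df[stats::complete.cases(df$day1, df$day2), ]
      if (drop_double_zero) df <- df[!(df$day1 == 0 & df$day2 == 0), ]
      if (nrow(df) < 3L || sd(df$day1) == 0 || sd(df$day2) == 0) {
        return(tibble::tibble(n = nrow(df), r = NA_real_, p = NA_real_,
                              icc21 = NA_real_))
      }
      ct <- cor.test(df$day1, df$day2)
      icc <- tryCatch(icc_2_1(cbind(df$day1, df$day2)),
                      capdyn_icc_undefined = function(e) NA_real_)
      tibble::tibble(n = nrow(df), r = unname(ct$estimate), p = ct$p.value,
                     icc21 = icc)
    }) |>
    dplyr::ungroup()
}

#' Three-axes state-trait variance table
#'
#' Coefficient of variation (sample SD / mean across subjects) of each
#' permutation-averaged metric, per CAP and per day. The per-day pair of
#' points places each CAP in the (CV FO, CV mean DT, CV var DT) space; the
#' displacement between days reads out the within-subject (state) variance.
#' Cells with non-positive mean have no defined CV and return `NA` with a
#' warning.
#'
#' @param agg Aggregated metrics from [aggregate_metrics()].
#' @param metrics Metric columns to summarise.
#'
#' @return Tibble with `state`, `day`, `metric`, `cv`, `mean`, `sd`.
#' @export
three_axes_table <- function(agg, metrics = c("fo", "mean_dt", "var_dt")) {
  long <- tidyr::pivot_longer(agg, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  out <- dplyr::group_by(long, .data$state, .data$day, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop") |>
    dplyr::mutate(cv = ifelse(.data$mean > 0, .data$sd / .data$mean, NA_real_))
  if (any(is.na(out$cv))) {
    warn("CV undefined (mean <= 0) for some CAP x metric x day cells")
  }
  dplyr::select(out, "state", "day", "metric", "cv", "mean", "sd")
}
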