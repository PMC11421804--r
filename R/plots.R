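#' Silhouette-versus-k curve with the selected knee
#'
#' @param scan A `cap_kscan` from [scan_k()].
#' @param k_hat Optional k-hat from [estimate_k()] to mark.
#' @return A ggplot.
#' @export
plot_silhouette <- function(scan, k_hat = NULL) {
  p <- ggplot2::ggplot(tibble::as_tibble(scan),
                       ggplot2::aes(x = .data$k, y = .data$silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters k", y = "mean silhouette width") +
    ggplot2::theme_minimal()
  if (!is.null(k_hat)) {
    p <- p + ggplot2::geom_vline(xintercept = as.integer(k_hat),
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Heatmap of basis CAP patterns
#'
#' @param object A `cap_basis`.
#' @param ... Unused.
#' @return A ggplot showing z-scored co-activation per parcel and CAP.
#' @export
autoplot.cap_basis <- function(object, ...) {
  pats <- object$patterns
  if (is.null(colnames(pats))) colnames(pats) <- paste0("p", seq_len(ncol(pats)))
  df <- tibble::as_tibble(pats, rownames = "cap") |>
    tidyr::pivot_longer(-"cap", names_to = "parcel", values_to = "z")
  df$parcel <- factor(df$parcel, levels = unique(df$parcel))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parcel, y = .data$cap,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick") +
    ggplot2::labs(x = "parcel", y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Three-axes state-trait variance plot (two projections)
#'
#' Plots each CAP's between-subject coefficient of variation of FO against
#' that of mean DT, one point per day, so the day-to-day displacement (state
#' variance) is visible.
#'
#' @param three_axes Output of [three_axes_table()].
#' @return A ggplot.
#' @export
plot_three_axes <- function(three_axes) {
  wide <- tidyr::pivot_wider(three_axes, id_cols = c("state", "day"),
                             names_from = "metric", values_from = "cv")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$fo, y = .data$mean_dt,
                                     colour = .data$state,
                                     shape = factor(.data$day))) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_line(ggplot2::aes(group = .data$state), linetype = "dotted") +
    ggplot2::labs(x = "CV of FO (across subjects)",
                  y = "CV of mean DT (across subjects)",
                  colour = "CAP", shape = "day") +
    ggplot2::theme_minimal()
}

#' Day-to-day reliability bar plot
#'
#' @param reliability Output of [day_reliability()].
#' @return A ggplot of Pearson r (bars) per CAP and metric.
#' @export
plot_reliability <- function(reliability) {
  ggplot2::ggplot(reliability,
                  ggplot2::aes(x = .data$state, y = .data$r,
                               fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "CAP", y = "between-day Pearson r", fill = "metric") +
    ggplot2::theme_minimal()
}

#' Delta-occurrence distribution by subgroup
#'
#' @param delta Output of [occurrence_stats()].
#' @param subgroups Tibble `subject_id`, `subgroup` (e.g. from ground truth
#'   or [cluster_subgroups()]).
#' @return A ggplot.
#' @export
plot_delta_occurrence <- function(delta, subgroups) {
  df <- dplyr::inner_join(delta, subgroups, by = "subject_id")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$subgroup),
                                   y = .data$delta_z)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = "subgroup", y = "Δ occurrence (z)") +
    ggplot2::theme_minimal()
}
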