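#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an axial slice of a CV map
#'
#' @param object A [cv_map()] result.
#' @param slice Axial slice index (default: middle slice).
#' @param ... Unused.
#' @return A ggplot raster of the CV values (invalid voxels blank).
#' @exportS3Method ggplot2::autoplot
autoplot.cv_map <- function(object, slice = NULL, ...) {
  d <- dim(object$data)
  if (is.null(slice)) slice <- ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$cv <- as.vector(object$data[, , slice])
  df$cv[!as.vector(object$valid[, , slice])] <- NA
  band <- if (is.null(object$band_hz)) "full band"
          else sprintf("%g-%g Hz", object$band_hz[1], object$band_hz[2])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$cv)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("CV map, slice %d (%s)", slice, band),
                  fill = "CV") +
    ggplot2::theme_minimal()
}

#' Plot per-stratum cohort comparison
#'
#' Group means with SD error bars per tissue and method, faceted by band;
#' the visual analogue of the cohort summary table.
#'
#' @param object A `cohort_report` from [compare_cohorts()].
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cohort_report <- function(object, ...) {
  g <- object$groups
  long <- object$strata |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(c(paste0("mean_", g), paste0("sd_", g))),
      names_to = c(".value", "group"), names_pattern = "(mean|sd)_(.*)")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = interaction(.data$tissue, .data$method),
                               y = .data$mean, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::facet_wrap(~ band, scales = "free_y") +
    ggplot2::labs(x = "tissue.method", y = "mean CV") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Band-contribution plot
#'
#' Mean band-limited CV per frequency band, by tissue and group: shows which
#' part of the spectrum carries the fluctuation amplitude.
#'
#' @param table Cohort tibble (as produced by [run_cohort()]) containing
#'   band-limited rows.
#' @param method Aggregation method to display.
#' @return A ggplot.
#' @export
plot_band_contribution <- function(table, method = "strict") {
  d <- table |>
    dplyr::filter(.data$method == !!method, .data$band != "full") |>
    dplyr::group_by(.data$group, .data$tissue, .data$band) |>
    dplyr::summarise(mean_cv = mean(.data$cv), sd_cv = stats::sd(.data$cv),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(.data$band, .data$mean_cv, fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_cv - .data$sd_cv,
                   ymax = .data$mean_cv + .data$sd_cv),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::facet_wrap(~ tissue) +
    ggplot2::labs(x = "frequency band", y = "mean band CV") +
    ggplot2::theme_minimal()
}
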