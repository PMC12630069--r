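#' Assemble the per-scenario system comparison
#'
#' Collects, per scenario and system, the boxplot statistics of the
#' per-spot median WET shifts (1.5 IQR whisker convention), the
#' accuracy/precision table, and the BEV range-shift-map data. Scenarios
#' present in the requested set but absent from the results are reported
#' in `$missing`, never silently skipped.
#'
#' @param res An `rv_experiment` from [run_experiment()], or a list with
#'   `summaries`, `stats`, and `shifts` tibbles of the same shape.
#' @param scenarios Scenario ids the report should cover.
#' @return A list of class `rv_report`: `box_data`, `stats`, `rsm_data`,
#'   `missing`.
#' @export
compare_report <- function(res, scenarios = sort(unique(res$stats$scenario))) {
  have <- unique(res$stats$scenario)
  missing <- setdiff(scenarios, have)
  summaries <- res$summaries[res$summaries$scenario %in% scenarios, ]
  box_data <- summaries |>
    filter(!is.na(.data$m_mm)) |>
    group_by(.data$scenario, .data$system) |>
    summarise(
      n = dplyr::n(),
      median_mm = iqr_box_stats(.data$m_mm)$median,
      q1_mm = iqr_box_stats(.data$m_mm)$q1,
      q3_mm = iqr_box_stats(.data$m_mm)$q3,
      whisker_lo_mm = iqr_box_stats(.data$m_mm)$whisker_lo,
      whisker_hi_mm = iqr_box_stats(.data$m_mm)$whisker_hi,
      n_outliers = length(iqr_box_stats(.data$m_mm)$outliers),
      .groups = "drop"
    )
  rsm_data <- res$shifts |>
    filter(.data$system == "RP", .data$scenario %in% scenarios) |>
    group_by(.data$scenario, .data$spot_id) |>
    summarise(m_mm = median(.data$shift_wet_mm[.data$flag == "ok"],
                            na.rm = TRUE), .groups = "drop")
  if (!is.null(res$rp_plan)) {
    rsm_data <- left_join(rsm_data,
                          select(as_tibble(res$rp_plan), "spot_id",
                                 "y_mm", "z_mm"), by = "spot_id")
  }
  structure(list(box_data = box_data,
                 stats = res$stats[res$stats$scenario %in% scenarios, ],
                 rsm_data = rsm_data, missing = missing),
            class = "rv_report")
}

#' @export
print.rv_report <- function(x, ...) {
  cat("<rv_report>\n")
  print(as.data.frame(x$stats), row.names = FALSE, digits = 4)
  if (length(x$missing)) {
    cat("missing scenarios:", paste(x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Boxplots of detected per-spot WET range shifts
#'
#' One box per scenario and system over the per-spot median WET shifts
#' (whiskers at 1.5 IQR, outliers as dots), with the ground truth G of
#' each scenario as a dashed line -- the standard way of presenting the
#' scenario comparison.
#'
#' @param object An `rv_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rv_experiment <- function(object, ...) {
  d <- filter(object$summaries, !is.na(.data$m_mm))
  g <- select(object$stats, "scenario", "system", "g_mm")
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$scenario),
                                  y = .data$m_mm,
                                  fill = .data$system)) +
    ggplot2::geom_boxplot(outlier.size = 0.6,
                          position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_point(data = g,
                        ggplot2::aes(y = .data$g_mm, group = .data$system),
                        position = ggplot2::position_dodge(width = 0.8),
                        shape = 95, size = 6, color = "black",
                        show.legend = FALSE) +
    ggplot2::labs(x = "scenario", y = "detected WET range shift [mm]",
                  fill = NULL,
                  title = "Spot-wise median WET range shifts",
                  subtitle = "black dash: ground truth G") +
    ggplot2::theme_minimal()
}

#' BEV color map of a range-shift map
#'
#' Renders the spot-median RP range shifts of one scenario on the 9 x 9
#' probe lattice in beam's eye view.
#'
#' @param res An `rv_experiment`.
#' @param scenario Scenario id to show.
#' @return A ggplot object.
#' @export
plot_rsm <- function(res, scenario) {
  rep_ <- compare_report(res, scenarios = scenario)
  ggplot2::ggplot(rep_$rsm_data,
                  ggplot2::aes(x = .data$z_mm, y = .data$y_mm,
                               fill = .data$m_mm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "shift [mm WET]") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "z (BEV left) [mm]", y = "y (BEV up) [mm]",
                  title = sprintf("RP range-shift map, scenario %d", scenario)) +
    ggplot2::theme_minimal()
}
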