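#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated blood-count trajectory
#'
#' @param object `hematotox_trajectory`
#' @param ... unused
#' @return ggplot: counts over time, one panel per analyte with its lower
#'   limit of normal
#' @export
autoplot.hematotox_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("PLT", "ANC", "WBC"),
                              names_to = "analyte", values_to = "value")
  lln <- dplyr::select(grading_rules(), "analyte", "lln")
  ggplot2::ggplot(long, ggplot2::aes(x = time, y = value)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_hline(data = lln, ggplot2::aes(yintercept = lln),
                        linetype = "dashed", color = "grey40") +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "count (1e9/L)") +
    ggplot2::theme_minimal()
}

#' Plot per-cycle grade-prediction deviations
#'
#' Bars of the mean absolute deviation between predicted and observed CTCAE
#' grades per cycle with standard-error whiskers, faceted by analyte (and
#' regimen when present). Cycle 1 (fitted, comparison only) is shown hollow.
#'
#' @param object `hematotox_deviation`
#' @param ... unused
#' @return ggplot
#' @export
autoplot.hematotox_deviation <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = factor(cycle), y = mean_abs_dev,
                                    alpha = !fitted_only)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(mean_abs_dev - se, 0),
                                        ymax = mean_abs_dev + se),
                           width = 0.25, na.rm = TRUE) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "cycle", y = "mean |predicted - observed| grade") +
    ggplot2::theme_minimal()
  facets <- intersect(c("analyte", "regimen"), names(object))
  if (length(facets) == 2) {
    p + ggplot2::facet_grid(regimen ~ analyte)
  } else if (length(facets) == 1) {
    p + ggplot2::facet_wrap(facets)
  } else {
    p
  }
}

#' Plot a fitted patient model against its cycle-1 data
#'
#' @param object `hematotox_fit`
#' @param observations the patient's observations (`time`, `analyte`,
#'   `value`)
#' @param params population parameters
#' @param ... unused
#' @return ggplot: model curve and observed points per analyte
#' @export
autoplot.hematotox_fit <- function(object, observations,
                                   params = default_parameters(), ...) {
  p_i <- set_individual(params, object$estimates)
  ev <- build_dosing_events(object$regimen, object$BSA, n_cycles = 1)
  grid <- seq(0, 14, by = 0.25)
  tr <- simulate_hematopoiesis(p_i, ev, grid)
  long <- tidyr::pivot_longer(tr, c("PLT", "ANC", "WBC"),
                              names_to = "analyte", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = time, y = value)) +
    ggplot2::geom_line(color = "darkorange") +
    ggplot2::geom_point(data = observations[observations$time < 14, ],
                        color = "navy") +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "count (1e9/L)",
                  title = paste("patient", object$patient_id)) +
    ggplot2::theme_minimal()
}
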