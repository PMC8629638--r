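#' Plot a payment-control sweep
#'
#' Average cost to society per patient (line, left) and hospital revenue
#' change per patient (line, right facet) against the control intensity.
#'
#' @param object A `control_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot control_sweep
#' @export
autoplot.control_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object$scenarios,
                              c("society_avg", "hospital_avg_delta"),
                              names_to = "measure", values_to = "usd")
  long$measure <- factor(long$measure,
                         levels = c("society_avg", "hospital_avg_delta"),
                         labels = c("society average cost",
                                    "hospital revenue change"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$intensity, y = .data$usd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::scale_x_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = "control intensity", y = "USD per patient",
                  title = paste0("DRG payment control sweep (",
                                 object$ruleset_name, ")")) +
    ggplot2::theme_minimal()
}

#' Plot per-group case-mix weight and coefficient of variation
#'
#' @param object A `group_summary` from [summarize_groups()].
#' @param ... Unused.
#' @return A ggplot: one bar panel for the case-mix weight (reference line at
#'   1) and one for the CV (homogeneity line at 1).
#' @method autoplot group_summary
#' @export
autoplot.group_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), c("weight", "cv"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$drg, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Case-mix weight and within-group CV") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a single-factor screen
#'
#' Bar chart of -log10 p-values per screened variable with the significance
#' threshold marked.
#'
#' @param screen Result of [screen_factors()].
#' @param alpha Significance level drawn as a reference line (default 0.05).
#' @return A ggplot.
#' @export
plot_factor_screen <- function(screen, alpha = 0.05) {
  d <- dplyr::filter(screen, .data$testable)
  d$neglog_p <- -log10(pmax(d$p_value, 1e-300))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$variable, .data$neglog_p),
                                  y = .data$neglog_p)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = "Single-factor screen of hospitalization cost") +
    ggplot2::theme_minimal()
}
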