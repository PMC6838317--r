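#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fecal contribution table
#'
#' Bar chart of per-taxon contributions to daily consumed biomass,
#' coloured by habitat category.
#'
#' @param object A [contribution_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot contribution_table
#' @export
autoplot.contribution_table <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(!is.na(.data$contribution))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$taxon, .data$contribution),
    y = .data$contribution, fill = .data$habitat
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Contribution to daily consumed biomass (%)",
      fill = "Habitat"
    ) +
    ggplot2::theme_minimal()
}

#' Plot mixing-model posterior dependence with HDR error bars
#'
#' @param object A `diet_posterior`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diet_posterior
#' @export
autoplot.diet_posterior <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(
    x = .data$source, y = 100 * .data$mean, fill = .data$group
  )) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * .data$hdr_low, ymax = 100 * .data$hdr_high),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::labs(
      x = NULL, y = "Dietary dependence (%)", fill = NULL,
      caption = sprintf("Error bars: %.0f%% highest-density region",
                        100 * object$hdr_mass)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a diet-switch TEF fit
#'
#' Observed isotopic offsets against days since the diet switch, the
#' fitted asymptotic exponential, and the estimated asymptote (TEF).
#'
#' @param object A `tef_fit`.
#' @param series The data the fit was computed from (columns `days`,
#'   `delta_diff`); required because the fit object stores the model, not
#'   the raw observations.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tef_fit
#' @export
autoplot.tef_fit <- function(object, series, ...) {
  grid <- tibble::tibble(days = seq(min(series$days), max(series$days),
                                    length.out = 200))
  a <- object$estimate[["A"]]
  b <- object$estimate[["B"]]
  cc <- object$estimate[["C"]]
  grid$fit <- if (is.na(b)) cc else a * exp(b * grid$days) + cc
  ggplot2::ggplot(series, ggplot2::aes(.data$days, .data$delta_diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = cc, linetype = "dashed") +
    ggplot2::labs(
      x = "Days since diet switch",
      y = expression(Delta * delta ~ "(‰)"),
      subtitle = sprintf("TEF (asymptote) = %.2f ± %.2f ‰",
                         object$tef, object$tef_se)
    ) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for an AICc-averaged model
#'
#' @param object An `averaged_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot averaged_model
#' @export
autoplot.averaged_model <- function(object, ...) {
  df <- dplyr::filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$estimate, y = stats::reorder(.data$term, .data$estimate)
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std_error,
      xmax = .data$estimate + 1.96 * .data$std_error
    )) +
    ggplot2::labs(
      x = "Model-averaged estimate (± 1.96 adjusted SE)", y = NULL,
      subtitle = paste0("Response: ", object$response)
    ) +
    ggplot2::theme_minimal()
}
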