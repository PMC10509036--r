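#' Trajectory plot of projected coverage
#'
#' Posterior-mean CCI trajectories with 95% credible ribbons, one panel per
#' unit (country or region), coloured by stratum level, with the coverage
#' target as a dashed reference line.
#'
#' @param object A `cci_projection` or `cci_regional` table.
#' @param units Optional subset of units to display.
#' @param target Reference line in % (default: the stored target).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cci_projection
#' @export
autoplot.cci_projection <- function(object, units = NULL, target = NULL, ...) {
  target <- target %||% attr(object, "target") %||% 80
  dat <- tibble::as_tibble(object)
  if (!is.null(units)) dat <- dplyr::filter(dat, .data$unit %in% units)
  ggplot2::ggplot(dat, ggplot2::aes(
    .data$year, .data$mean,
    colour = .data$stratum_level, fill = .data$stratum_level
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$cri_low, ymax = .data$cri_high),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = target, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$unit)) +
    ggplot2::labs(
      x = NULL, y = "Composite coverage index (%)",
      colour = "Stratum", fill = "Stratum"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cci_projection
#' @method autoplot cci_regional
#' @export
autoplot.cci_regional <- autoplot.cci_projection

#' Trace plot of posterior draws
#'
#' @param object A `cci_fit`.
#' @param parameters Parameters to display (default: the fixed effects).
#' @param ... Unused.
#' @return A ggplot object with one panel per parameter, coloured by chain.
#' @method autoplot cci_fit
#' @export
autoplot.cci_fit <- function(object, parameters = NULL, ...) {
  parameters <- parameters %||% object$fixed_names
  dat <- purrr::imap(object$draws, function(m, chain) {
    tibble::as_tibble(m[, parameters, drop = FALSE]) |>
      dplyr::mutate(chain = factor(chain), iteration = dplyr::row_number())
  }) |>
    dplyr::bind_rows() |>
    tidyr::pivot_longer(dplyr::all_of(parameters),
      names_to = "parameter", values_to = "value"
    )
  ggplot2::ggplot(dat, ggplot2::aes(.data$iteration, .data$value, colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_y") +
    ggplot2::labs(x = "Kept iteration", y = NULL, colour = "Chain") +
    ggplot2::theme_minimal()
}

#' Equiplot-style view of inequality over time
#'
#' @param ineq Output of [inequality_table()].
#' @param units Optional subset of units.
#' @return A ggplot object: inequality metric vs year, one line per unit.
#' @export
plot_inequality <- function(ineq, units = NULL) {
  dat <- tibble::as_tibble(ineq)
  if (!is.null(units)) dat <- dplyr::filter(dat, .data$unit %in% units)
  ggplot2::ggplot(dat, ggplot2::aes(.data$year, .data$value, group = .data$unit)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$cri_low, ymax = .data$cri_high),
      alpha = 0.15
    ) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(ggplot2::vars(.data$unit)) +
    ggplot2::labs(
      x = NULL,
      y = paste0(unique(dat$metric), " (percentage points)")
    ) +
    ggplot2::theme_minimal()
}
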