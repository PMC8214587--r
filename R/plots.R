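#' Plot a cohort trace
#'
#' State occupancy (PFS, PD, dead) over the model horizon.
#'
#' @param trace A `cohort_trace`.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  long <- trace |>
    as_tibble() |>
    select("cycle", "pfs", "pd", "dead") |>
    pivot_longer(c("pfs", "pd", "dead"), names_to = "state",
                 values_to = "occupancy")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$occupancy,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cycle (months)", y = "State occupancy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) plot_trace(object)

#' Tornado diagram of a one-way sensitivity analysis
#'
#' Horizontal bars from the low-bound to the high-bound ICER for the most
#' influential parameters, with the base-case ICER as a vertical reference.
#' Legs flagged as dominated are drawn at the plot boundary with an asterisk
#' appended to the parameter label rather than as a fabricated ICER.
#'
#' @param result An `owsa_result` from [owsa()].
#' @param n_parameters How many top-ranked parameters to show (default 15).
#' @param wtp Willingness-to-pay boundary used to place dominated legs.
#' @return A ggplot object.
#' @export
plot_tornado <- function(result, n_parameters = 15, wtp = 100000) {
  base_icer <- attr(result, "base_icer")
  dat <- result |>
    filter(.data$rank <= n_parameters) |>
    mutate(
      flagged = .data$dominance_low != "none" | .data$dominance_high != "none",
      label = ifelse(.data$flagged, paste0(.data$parameter, " *"),
                     .data$parameter),
      icer_low_plot = ifelse(is.na(.data$icer_low), wtp, .data$icer_low),
      icer_high_plot = ifelse(is.na(.data$icer_high), wtp, .data$icer_high)
    ) |>
    arrange(.data$range_chf) |>
    mutate(label = factor(.data$label, levels = .data$label))
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$icer_low_plot, xend = .data$icer_high_plot,
                   y = .data$label, yend = .data$label),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(x = "ICER (CHF per QALY gained)", y = NULL,
                  caption = "* dominance in at least one leg") +
    ggplot2::theme_minimal()
}

#' @method autoplot owsa_result
#' @export
autoplot.owsa_result <- function(object, ...) plot_tornado(object, ...)

#' Cost-effectiveness acceptability curves
#'
#' Probability each strategy is optimal (highest net monetary benefit) as a
#' function of willingness-to-pay.
#'
#' @param x A `psa_result` or a CEAC tibble from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(x) {
  dat <- if (inherits(x, "psa_result")) x$ceac else x
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                    colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay (CHF per QALY)",
                  y = "Probability cost-effective", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot psa_result
#' @export
autoplot.psa_result <- function(object, ...) plot_ceac(object)

#' Plot a parametric fit against the Kaplan-Meier estimate
#'
#' Visual-fit companion to AIC/BIC selection: the KM step function of the
#' data with the fitted survivor overlaid over the model horizon.
#'
#' @param fit A `surv_fit`.
#' @param ipd The `(time, event)` records the model was fitted to.
#' @param horizon_months Extrapolation span (default 120).
#' @return A ggplot object.
#' @export
plot_survival_fit <- function(fit, ipd, horizon_months = 120) {
  km <- km_estimate(ipd, sort(unique(c(0, ipd$time))))
  grid <- seq(0, horizon_months, by = 0.5)
  par_curve <- tibble(time = grid, surv = survivor(fit$model, grid))
  ggplot2::ggplot() +
    ggplot2::geom_step(data = km,
                       ggplot2::aes(x = .data$time, y = .data$surv),
                       colour = "grey40") +
    ggplot2::geom_line(data = par_curve,
                       ggplot2::aes(x = .data$time, y = .data$surv),
                       colour = "firebrick") +
    ggplot2::labs(x = "Months", y = "Survival",
                  subtitle = paste0(fit$family, " fit (AIC ",
                                    round(fit$aic, 1), ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
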