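#' Discount factor for a model cycle
#'
#' Continuous-per-cycle convention: cycle `t` is discounted at its midpoint
#' `(t + 0.5)/12` years when half-cycle correction is on, and at `t/12` years
#' otherwise.
#'
#' @param rate_annual Annual discount rate (>= 0).
#' @param cycle Cycle index (0-based; vectorized).
#' @param half_cycle_correction Use the cycle midpoint.
#' @return Discount factors in `(0, 1]`.
#' @examples
#' discount_factor(0.03, 12, half_cycle_correction = FALSE) # 1/1.03
#' @export
discount_factor <- function(rate_annual, cycle, half_cycle_correction = TRUE) {
  stopifnot(rate_annual >= 0, all(cycle >= 0))
  offset <- if (half_cycle_correction) 0.5 else 0
  (1 + rate_annual)^(-(cycle + offset) / 12)
}

# overlap in months of the cycle window [m, m+1) with a component window
# [from, to); fractional treatment durations (2.76, 4.2, 5.2 months) are
# pro-rated in the boundary cycle rather than rounded
month_overlap <- function(m, from, to) {
  pmax(0, pmin(to, m + 1) - pmax(from, m))
}

component_rate <- function(component, costs) {
  unit <- costs$unit_chf_per_month[[component$cost_key]]
  if (is.null(unit)) {
    abort(paste0("Unknown cost_key '", component$cost_key, "'."),
          class = "markovcea_config_error")
  }
  unit * (component$multiplier %||% 1)
}

# per-cycle CHF for a list of components over months 0..horizon-1, optionally
# truncating every component window at `truncate_at`
components_profile <- function(components, costs, horizon, truncate_at = Inf,
                               kinds = NULL) {
  m <- 0:(horizon - 1)
  out <- numeric(horizon)
  for (cm in components) {
    if (!is.null(kinds) && !cm$kind %in% kinds) next
    out <- out + component_rate(cm, costs) *
      month_overlap(m, cm$from_month, pmin(cm$to_month, truncate_at))
  }
  out
}

#' Second-line cost profile by tunnel age
#'
#' Cost per month of progressive disease as a function of tunnel age (months
#' since progression). The share `p_second_line` of progressors receives the
#' strategy's second-line components while tunnel age is below both each
#' component's duration and the fixed second-line progression time, and best
#' supportive care afterwards; the remaining share receives BSC from tunnel
#' age 0. Fractional durations are pro-rated within the boundary month.
#'
#' @param strategy A strategy configuration.
#' @param costs The `costs` element of the configuration.
#' @param horizon Number of tunnel ages to tabulate.
#' @return A tibble with `tunnel_age`, `second_line_chf` (active 2L
#'   components, uptake-scaled) and `bsc_chf` (BSC cost, both shares).
#' @export
second_line_cost_profile <- function(strategy, costs, horizon = 120) {
  p2l <- strategy$p_second_line
  s2_end <- strategy$second_line_pfs_months
  active <- components_profile(strategy$second_line, costs, horizon,
                               truncate_at = s2_end)
  m <- 0:(horizon - 1)
  bsc_unit <- costs$unit_chf_per_month$bsc
  # BSC: the (1 - p2l) share from age 0, the 2L share after 2L progression
  bsc <- bsc_unit * ((1 - p2l) + p2l * month_overlap(m, s2_end, Inf))
  tibble(
    tunnel_age = m,
    second_line_chf = p2l * active,
    bsc_chf = bsc
  )
}

# utility per month of PD by tunnel age: 2L-specific utility while on active
# second-line treatment, BSC utility otherwise
pd_utility_profile <- function(strategy, utilities, horizon = 120) {
  p2l <- strategy$p_second_line
  u_2l <- utilities$pd_second_line[[strategy$second_line_utility_key]]
  if (is.null(u_2l)) {
    abort(paste0("No PD utility for 2L category '",
                 strategy$second_line_utility_key, "'."),
          class = "markovcea_config_error")
  }
  u_bsc <- utilities$bsc
  w_active <- month_overlap(0:(horizon - 1), 0,
                            strategy$second_line_pfs_months)
  p2l * (u_2l * w_active + u_bsc * (1 - w_active)) + (1 - p2l) * u_bsc
}

# incidence-weighted one-off adverse-event cost of first-line treatment
ae_cost_total <- function(strategy, costs) {
  inc <- unlist(strategy$ae_incidence)
  unit <- unlist(costs$ae_unit_chf)[names(inc)]
  if (anyNA(unit)) {
    abort("Adverse-event categories of strategy and cost set do not match.",
          class = "markovcea_config_error")
  }
  sum(inc * unit) * (strategy$ae_cost_multiplier %||% 1)
}

#' Accrue costs and QALYs over a cohort trace
#'
#' Per-cycle rewards are occupancy times state reward times discount factor.
#' First-line costs accrue to PFS occupants while each regimen component is
#' on treatment (or, in time-on-treatment costing mode, drug and
#' administration components are weighted by the strategy's ToT survivor
#' curve while health-state occupancy is unchanged); second-line and BSC
#' costs accrue to PD occupants through the tunnel-age cost profile; the
#' end-of-life cost is a one-off applied to new deaths at their death
#' cycle's discount factor; the adverse-event burden of first-line treatment
#' is a one-off at model entry.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param costs,utilities Elements of the configuration.
#' @param settings A [model_settings] (or config `settings` list).
#' @param strategy The strategy configuration the trace was run for.
#' @return A one-row `strategy_outcome` tibble: discounted total cost and
#'   per-category costs (CHF), `qalys`, discounted and undiscounted life
#'   years, time in state (months) and the proportion dead at the horizon.
#' @export
accrue <- function(trace, costs, utilities, settings, strategy) {
  settings <- as_model_settings(settings)
  horizon <- settings$horizon_cycles
  if (nrow(trace) != horizon + 1) {
    abort("Trace and settings horizons do not match.",
          class = "markovcea_input_error")
  }
  hcc <- settings$half_cycle_correction
  df <- discount_factor(settings$discount_rate_annual, 0:(horizon - 1), hcc)

  pfs_occ <- cycle_occupancy(trace$pfs, hcc)
  pd_occ <- cycle_occupancy(trace$pd, hcc)
  tunnel <- attr(trace, "pd_tunnel")
  tun_occ <- if (hcc) {
    (tunnel[-nrow(tunnel), , drop = FALSE] +
       tunnel[-1, , drop = FALSE]) / 2
  } else {
    tunnel[-nrow(tunnel), , drop = FALSE]
  }

  # --- first line -----------------------------------------------------------
  if (settings$tot_costing) {
    if (is.null(strategy$tot)) {
      abort("tot_costing requires a time-on-treatment curve in the strategy.",
            class = "markovcea_config_error")
    }
    tot_model <- parametric_survival(strategy$tot$family, strategy$tot$params)
    tot_occ <- cycle_occupancy(survivor(tot_model, 0:horizon), hcc)
    on_treatment <- components_profile(strategy$first_line, costs, horizon,
                                       kinds = c("drug", "admin"))
    other <- components_profile(strategy$first_line, costs, horizon,
                                kinds = "diagnostics")
    cost_first_line <- sum(df * (on_treatment * tot_occ + other * pfs_occ))
  } else {
    f1 <- components_profile(strategy$first_line, costs, horizon)
    cost_first_line <- sum(df * f1 * pfs_occ)
  }

  # --- progressive disease: 2L and BSC through tunnel age -------------------
  profile <- second_line_cost_profile(strategy, costs, horizon)
  cost_second_line <- sum(df * as.vector(tun_occ %*% profile$second_line_chf))
  cost_bsc <- sum(df * as.vector(tun_occ %*% profile$bsc_chf))

  # --- one-offs -------------------------------------------------------------
  cost_ae <- ae_cost_total(strategy, costs)
  cost_eol <- costs$end_of_life_chf * sum(df * trace$new_deaths[-1])

  # --- life years and QALYs -------------------------------------------------
  alive_occ <- pfs_occ + pd_occ
  lys_discounted <- sum(df * alive_occ) / 12
  lys_undiscounted <- sum(alive_occ) / 12
  u_pd <- pd_utility_profile(strategy, utilities, horizon)
  qaly_flow <- utilities$pfs_first_line * pfs_occ +
    as.vector(tun_occ %*% u_pd)
  qalys <- sum(df * qaly_flow) / 12

  st <- state_times(trace, settings)
  out <- tibble(
    strategy = strategy$name,
    total_cost_chf = cost_first_line + cost_ae + cost_second_line +
      cost_bsc + cost_eol,
    cost_first_line_chf = cost_first_line,
    cost_adverse_events_chf = cost_ae,
    cost_second_line_chf = cost_second_line,
    cost_bsc_chf = cost_bsc,
    cost_end_of_life_chf = cost_eol,
    qalys = qalys,
    lys_discounted = lys_discounted,
    lys_undiscounted = lys_undiscounted,
    months_in_pfs = st$months_in_pfs,
    months_in_pd = st$months_in_pd,
    proportion_dead = st$proportion_dead_at_horizon
  )
  class(out) <- c("strategy_outcome", class(out))
  out
}

#' Run one strategy of a configuration end to end
#'
#' @param config A validated `cea_config`.
#' @param strategy_name Name of the strategy to run.
#' @return A one-row `strategy_outcome` tibble.
#' @export
run_strategy <- function(config, strategy_name) {
  strategy <- config$strategies[[strategy_name]]
  if (is.null(strategy)) {
    abort(paste0("No strategy '", strategy_name, "' in configuration."),
          class = "markovcea_config_error")
  }
  settings <- as_model_settings(config$settings)
  trace <- run_cohort(strategy, settings)
  accrue(trace, config$costs, config$utilities, settings, strategy)
}

#' Run every strategy of a configuration
#'
#' The base-case model run: one outcome row per strategy, in configuration
#' order.
#'
#' @param config A validated `cea_config`.
#' @return A `strategy_outcome` tibble with one row per strategy.
#' @examples
#' \donttest{
#' cfg <- generate_paramset(seed = 1)
#' run_model(cfg)
#' }
#' @export
run_model <- function(config) {
  out <- bind_rows(lapply(names(config$strategies),
                          function(nm) run_strategy(config, nm)))
  class(out) <- c("strategy_outcome", class(out))
  out
}
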