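#' Model settings
#'
#' Run settings of the cohort model: monthly cycles, horizon in cycles
#' (default 120 = 10 years), annual discount rate (default 3%) and half-cycle
#' correction (default on).
#'
#' @param horizon_cycles Number of monthly cycles.
#' @param discount_rate_annual Annual discount rate for costs and QALYs.
#' @param half_cycle_correction Average start- and end-of-cycle occupancy
#'   when accruing rewards.
#' @param tot_costing Weight first-line drug/administration costs by a
#'   time-on-treatment survivor curve instead of PFS occupancy.
#' @param wtp_chf_per_qaly Willingness-to-pay threshold (CHF/QALY).
#' @return A `model_settings` list.
#' @export
model_settings <- function(horizon_cycles = 120, discount_rate_annual = 0.03,
                           half_cycle_correction = TRUE, tot_costing = FALSE,
                           wtp_chf_per_qaly = 100000) {
  if (horizon_cycles < 1) {
    abort("horizon_cycles must be >= 1.", class = "markovcea_config_error")
  }
  if (discount_rate_annual < 0) {
    abort("discount_rate_annual must be >= 0.",
          class = "markovcea_config_error")
  }
  structure(list(
    cycle_length_months = 1,
    horizon_cycles = as.integer(horizon_cycles),
    discount_rate_annual = discount_rate_annual,
    half_cycle_correction = isTRUE(half_cycle_correction),
    tot_costing = isTRUE(tot_costing),
    wtp_chf_per_qaly = wtp_chf_per_qaly
  ), class = "model_settings")
}

as_model_settings <- function(x) {
  if (inherits(x, "model_settings")) return(x)
  model_settings(
    horizon_cycles = x$horizon_cycles,
    discount_rate_annual = x$discount_rate_annual,
    half_cycle_correction = x$half_cycle_correction %||% TRUE,
    tot_costing = x$tot_costing %||% FALSE,
    wtp_chf_per_qaly = x$wtp_chf_per_qaly %||% 100000
  )
}

#' Derive per-cycle state-transition probabilities from two schedules
#'
#' The overall-survival exit probability is applied as a single per-cycle
#' death probability to every alive state (PFS and PD alike), so the model's
#' all-cause survival reproduces the fitted OS curve exactly at every cycle
#' boundary. Progression is the residual of the PFS exit probability:
#' `p_pfs_to_pd = max(0, pfs_exit - p_death)`. Cycles where independently
#' fitted curves cross (PFS exit below the death probability) are floored at
#' zero progression and reported via a warning.
#'
#' @param pfs_schedule,os_schedule Transition schedules from
#'   [to_transition_schedule()], of equal length.
#' @return A tibble with `cycle`, `p_death`, `p_pfs_to_pd`, `p_pfs_exit`,
#'   with the number of floored cycles in attribute `"floored"`.
#' @export
derive_state_transitions <- function(pfs_schedule, os_schedule) {
  if (nrow(pfs_schedule) != nrow(os_schedule)) {
    abort("PFS and OS schedules must have equal length.",
          class = "markovcea_input_error")
  }
  p_death <- os_schedule$tp
  pfs_exit <- pfs_schedule$tp
  raw <- pfs_exit - p_death
  floored <- sum(raw < 0)
  if (floored > 0) {
    warn(paste0("PFS exit probability below death probability in ", floored,
                " cycle(s); progression floored at 0."))
  }
  out <- tibble(
    cycle = os_schedule$cycle,
    p_death = p_death,
    p_pfs_to_pd = pmax(raw, 0),
    p_pfs_exit = pfs_exit
  )
  attr(out, "floored") <- floored
  out
}

#' Run the 3-state Markov cohort model
#'
#' Simulates a cohort starting entirely in the progression-free (PFS) state
#' through monthly cycles across PFS, progressive disease (PD) and death.
#' PD occupancy is tracked by tunnel age (months since progression) so that
#' second-line costs and utilities can depend on time since progression
#' without violating the Markov property; tunnel age does not alter
#' transition probabilities. Transitions are evaluated at cycle start;
#' cycle `t` spans months `(t, t + 1]`.
#'
#' @param strategy A strategy configuration (an element of
#'   `config$strategies`) carrying `os` and `pfs` model specifications.
#' @param settings A [model_settings] object (or the `settings` element of a
#'   configuration).
#' @return A `cohort_trace`: a tibble with one row per cycle boundary
#'   (`cycle` = 0..horizon) and columns `pfs`, `pd`, `dead`, `new_deaths`,
#'   `new_progressions`; the PD-by-tunnel-age matrix is in attribute
#'   `"pd_tunnel"` (rows = boundaries, columns = tunnel age 0-based).
#' @export
run_cohort <- function(strategy, settings) {
  settings <- as_model_settings(settings)
  horizon <- settings$horizon_cycles
  os <- parametric_survival(strategy$os$family, strategy$os$params)
  pfs <- parametric_survival(strategy$pfs$family, strategy$pfs$params)
  trans <- derive_state_transitions(
    to_transition_schedule(pfs, horizon),
    to_transition_schedule(os, horizon)
  )
  markov_trace(trans, horizon, settings)
}

#' Cohort trace from explicit transition probabilities
#'
#' Lower-level engine behind [run_cohort()], useful for oracle checks with
#' hand-built probabilities.
#'
#' @param transitions Tibble with `p_death` and `p_pfs_to_pd` per cycle.
#' @param horizon_cycles Number of cycles to run (must not exceed the
#'   schedule length).
#' @param settings Optional [model_settings] stored on the trace.
#' @return A `cohort_trace` (see [run_cohort()]).
#' @export
markov_trace <- function(transitions, horizon_cycles,
                         settings = model_settings(horizon_cycles)) {
  if (nrow(transitions) < horizon_cycles) {
    abort("Transition schedule shorter than the horizon.",
          class = "markovcea_config_error")
  }
  q_d <- transitions$p_death[seq_len(horizon_cycles)]
  q_p <- transitions$p_pfs_to_pd[seq_len(horizon_cycles)]

  n_b <- horizon_cycles + 1L
  pfs <- numeric(n_b); dead <- numeric(n_b)
  new_deaths <- numeric(n_b); new_prog <- numeric(n_b)
  tunnel <- matrix(0, nrow = n_b, ncol = horizon_cycles)
  pfs[1] <- 1

  for (t in seq_len(horizon_cycles)) {
    prev_pfs <- pfs[t]
    prev_tun <- tunnel[t, ]
    d <- (prev_pfs + sum(prev_tun)) * q_d[t]
    np <- prev_pfs * q_p[t]
    pfs[t + 1] <- prev_pfs * (1 - q_d[t] - q_p[t])
    tunnel[t + 1, 1] <- np
    if (horizon_cycles > 1) {
      tunnel[t + 1, 2:horizon_cycles] <-
        prev_tun[1:(horizon_cycles - 1)] * (1 - q_d[t])
    }
    dead[t + 1] <- dead[t] + d
    new_deaths[t + 1] <- d
    new_prog[t + 1] <- np
  }

  out <- tibble(
    cycle = 0:horizon_cycles,
    pfs = pfs,
    pd = rowSums(tunnel),
    dead = dead,
    new_deaths = new_deaths,
    new_progressions = new_prog
  )
  attr(out, "pd_tunnel") <- tunnel
  attr(out, "settings") <- settings
  class(out) <- c("cohort_trace", class(out))
  out
}

#' Time-in-state summaries of a cohort trace
#'
#' Undiscounted mean months per alive state (half-cycle corrected when the
#' trace's settings say so) and the fraction of the cohort dead at the
#' horizon.
#'
#' @param trace A `cohort_trace`.
#' @param settings Optional override of the settings stored on the trace.
#' @return A one-row tibble: `months_in_pfs`, `months_in_pd`,
#'   `proportion_dead_at_horizon`.
#' @export
state_times <- function(trace, settings = NULL) {
  settings <- as_model_settings(settings %||% attr(trace, "settings"))
  w_pfs <- cycle_occupancy(trace$pfs, settings$half_cycle_correction)
  w_pd <- cycle_occupancy(trace$pd, settings$half_cycle_correction)
  tibble(
    months_in_pfs = sum(w_pfs),
    months_in_pd = sum(w_pd),
    proportion_dead_at_horizon = trace$dead[nrow(trace)]
  )
}

# per-cycle occupancy weight: mean of start/end boundary under half-cycle
# correction, start-of-cycle occupancy otherwise
cycle_occupancy <- function(boundary_values, half_cycle_correction) {
  n <- length(boundary_values)
  if (half_cycle_correction) {
    (boundary_values[-n] + boundary_values[-1]) / 2
  } else {
    boundary_values[-n]
  }
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("<cohort_trace> ", nrow(x) - 1, " monthly cycles; final occupancy: ",
      "PFS ", signif(x$pfs[nrow(x)], 4), ", PD ", signif(x$pd[nrow(x)], 4),
      ", dead ", signif(x$dead[nrow(x)], 4), "\n", sep = "")
  NextMethod()
}
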