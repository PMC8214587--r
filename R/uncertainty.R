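#' Parameter distributions for sensitivity analyses
#'
#' Builds the standard 33-parameter uncertainty set over a configuration:
#' per strategy the survival-curve parameters (OS log rate, PFS meanlog and
#' log sdlog; 9), the nine unit costs (8 per-cycle unit costs plus the
#' end-of-life one-off), the three first-line adverse-event cost totals (as
#' multipliers), the five utilities, the discount rate, the three
#' second-line uptake probabilities and the three second-line progression
#' times.
#'
#' Distribution families follow the usual conventions: gamma for costs and
#' durations, beta for utilities and probabilities, normal on the
#' unconstrained (log where positive) scale for survival parameters; the
#' discount rate is varied only in one-way analysis (family `"none"`).
#' One-way bounds are 95% intervals of the corresponding distribution
#' (an explicit 0-5% range for the discount rate).
#'
#' @param config A validated `cea_config`.
#' @return A tibble with columns `parameter` (label), `path`, `central`,
#'   `low`, `high`, `family`, `scale_par` (se on the sampling scale for
#'   normal, coefficient of variation for gamma, effective sample size for
#'   beta).
#' @export
owsa_parameters <- function(config) {
  psa <- config$psa
  rows <- list()
  add <- function(parameter, path, family, scale_par,
                  low = NULL, high = NULL) {
    central <- config_get(config, path)
    if (is.null(low)) {
      ci <- param_bounds(central, family, scale_par)
      low <- ci[1]; high <- ci[2]
    }
    rows[[length(rows) + 1]] <<- tibble(
      parameter = parameter, path = path, central = central,
      low = low, high = high, family = family, scale_par = scale_par
    )
  }

  for (nm in names(config$strategies)) {
    st <- config$strategies[[nm]]
    if (st$os$family == "exponential") {
      add(paste0("OS rate (", nm, ")"),
          paste0("strategies.", nm, ".os.params.rate"),
          "normal_log", psa$survival_log_se)
    } else {
      add(paste0("OS meanlog (", nm, ")"),
          paste0("strategies.", nm, ".os.params.meanlog"),
          "normal", psa$pfs_meanlog_se)
    }
    add(paste0("PFS meanlog (", nm, ")"),
        paste0("strategies.", nm, ".pfs.params.meanlog"),
        "normal", psa$pfs_meanlog_se)
    add(paste0("PFS sdlog (", nm, ")"),
        paste0("strategies.", nm, ".pfs.params.sdlog"),
        "normal_log", psa$survival_log_se)
  }
  for (ck in names(config$costs$unit_chf_per_month)) {
    add(paste0("Unit cost: ", ck, " (CHF/month)"),
        paste0("costs.unit_chf_per_month.", ck), "gamma", psa$cost_cv)
  }
  add("End-of-life cost (CHF)", "costs.end_of_life_chf", "gamma", psa$cost_cv)
  for (nm in names(config$strategies)) {
    add(paste0("1L AE costs (", nm, ")"),
        paste0("strategies.", nm, ".ae_cost_multiplier"),
        "gamma", psa$cost_cv)
  }
  add("Utility PFS on 1L", "utilities.pfs_first_line", "beta", psa$utility_nu)
  for (uk in names(config$utilities$pd_second_line)) {
    add(paste0("Utility PD on 2L ", uk),
        paste0("utilities.pd_second_line.", uk), "beta", psa$utility_nu)
  }
  add("Utility BSC", "utilities.bsc", "beta", psa$utility_nu)
  add("Discount rate", "settings.discount_rate_annual", "none", NA_real_,
      low = 0, high = 0.05)
  for (nm in names(config$strategies)) {
    add(paste0("2L uptake (", nm, ")"),
        paste0("strategies.", nm, ".p_second_line"),
        "beta", psa$p_second_line_nu)
    add(paste0("2L progression time (", nm, ", months)"),
        paste0("strategies.", nm, ".second_line_pfs_months"),
        "gamma", psa$duration_cv)
  }
  bind_rows(rows)
}

# 95% interval of the one-way range for a central value under a family
param_bounds <- function(central, family, scale_par) {
  switch(family,
    normal_log = exp(log(central) + c(-1, 1) * 1.96 * scale_par),
    normal = central + c(-1, 1) * 1.96 * scale_par,
    gamma = {
      if (central <= 0) c(0, 0) else {
        shape <- 1 / scale_par^2
        stats::qgamma(c(0.025, 0.975), shape = shape,
                      rate = shape / central)
      }
    },
    beta = {
      a <- central * scale_par; b <- (1 - central) * scale_par
      stats::qbeta(c(0.025, 0.975), a, b)
    },
    none = c(central, central)
  )
}

draw_parameter <- function(central, family, scale_par, n) {
  switch(family,
    normal_log = exp(rnorm(n, log(central), scale_par)),
    normal = rnorm(n, central, scale_par),
    gamma = {
      if (central <= 0) rep(0, n) else {
        shape <- 1 / scale_par^2
        rgamma(n, shape = shape, rate = shape / central)
      }
    },
    beta = rbeta(n, central * scale_par, (1 - central) * scale_par),
    none = rep(central, n)
  )
}

#' One-way sensitivity analysis (tornado)
#'
#' Re-runs the compared strategies with each parameter at its lower and
#' upper bound, all other parameters held central, and ranks parameters by
#' the width of the resulting ICER range. Legs where one strategy dominates
#' are flagged rather than coerced to a number, and a leg whose
#' configuration fails validation is recorded as a failed leg rather than
#' silently dropped. The top 15 parameters are marked for tornado plotting.
#'
#' @param config A validated `cea_config`.
#' @param parameters A parameter table from [owsa_parameters()] (default).
#' @param strategy,comparator The compared pair (default: combination vs
#'   pembrolizumab).
#' @return An `owsa_result` tibble: `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `dominance_low`, `dominance_high`, `range_chf`, `rank`,
#'   `top15`; the base-case ICER is in attribute `"base_icer"`.
#' @export
owsa <- function(config, parameters = owsa_parameters(config),
                 strategy = "combination", comparator = "pembrolizumab") {
  eval_icer <- function(cfg) {
    outs <- suppressWarnings(
      bind_rows(run_strategy(cfg, strategy),
                run_strategy(cfg, comparator))
    )
    inc <- incrementals(outs, strategy, comparator)
    ic <- icer(inc$delta_total_cost_chf, inc$delta_qalys)
    list(icer = ic$icer, dominance = ic$dominance)
  }
  base <- eval_icer(config)

  leg <- function(path, value) {
    tryCatch({
      cfg <- config_set(config, path, value)
      eval_icer(cfg)
    }, error = function(e) list(icer = NA_real_, dominance = "failed_leg"))
  }
  rows <- purrr::pmap(parameters, function(parameter, path, central, low,
                                           high, family, scale_par) {
    lo <- leg(path, low)
    hi <- leg(path, high)
    tibble(
      parameter = parameter, path = path, low = low, high = high,
      icer_low = lo$icer, icer_high = hi$icer,
      dominance_low = lo$dominance, dominance_high = hi$dominance,
      range_chf = abs(hi$icer - lo$icer)
    )
  })
  out <- bind_rows(rows) |>
    arrange(desc(.data$range_chf)) |>
    mutate(rank = row_number(), top15 = .data$rank <= 15)
  attr(out, "base_icer") <- base$icer
  attr(out, "comparison") <- c(strategy = strategy, comparator = comparator)
  class(out) <- c("owsa_result", class(out))
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws every uncertain parameter from its distribution, re-evaluates the
#' full model per draw, and assembles the cost-effectiveness acceptability
#' curve over a willingness-to-pay grid. Draws producing an invalid
#' configuration are redrawn (with a logged count, capped at 100 consecutive
#' rejections).
#'
#' @param config A validated `cea_config`.
#' @param parameters A parameter table from [owsa_parameters()].
#' @param n_draws Number of Monte-Carlo draws (default from
#'   `config$psa$n_draws`).
#' @param wtp_grid Willingness-to-pay grid in CHF/QALY.
#' @param seed Integer seed; the full analysis is reproducible given the
#'   seed.
#' @return A `psa_result` list: `draws` (tibble `draw`, `strategy`, `cost`,
#'   `qaly`), `ceac` (from [ceac()]), `wtp_grid`, `seed`, `n_redrawn`.
#' @export
psa <- function(config, parameters = owsa_parameters(config),
                n_draws = config$psa$n_draws %||% 1000,
                wtp_grid = seq(0, 250000, by = 10000), seed = 1) {
  if (n_draws < 1 || length(wtp_grid) == 0) {
    abort("psa() needs n_draws >= 1 and a non-empty wtp_grid.",
          class = "markovcea_input_error")
  }
  strategies <- names(config$strategies)
  n_redrawn <- 0L
  draws <- with_seed(seed, {
    res <- vector("list", n_draws)
    for (i in seq_len(n_draws)) {
      attempt <- 0L
      repeat {
        attempt <- attempt + 1L
        if (attempt > 100L) {
          abort("More than 100 consecutive invalid PSA draws.",
                class = "markovcea_psa_error")
        }
        vals <- purrr::pmap_dbl(
          parameters[c("central", "family", "scale_par")],
          function(central, family, scale_par) {
            draw_parameter(central, family, scale_par, 1)
          }
        )
        cfg <- config
        for (j in seq_len(nrow(parameters))) {
          cfg <- config_set(cfg, parameters$path[j], vals[j])
        }
        out <- tryCatch(
          suppressWarnings(run_model(cfg)),
          error = function(e) NULL
        )
        if (!is.null(out)) break
        n_redrawn <- n_redrawn + 1L
      }
      res[[i]] <- tibble(draw = i, strategy = out$strategy,
                         cost = out$total_cost_chf, qaly = out$qalys)
    }
    bind_rows(res)
  })
  if (n_redrawn > 0) {
    inform(paste0(n_redrawn, " PSA draw(s) were rejected and redrawn."))
  }
  structure(list(
    draws = draws,
    ceac = ceac(draws, wtp_grid),
    wtp_grid = wtp_grid,
    seed = as.integer(seed),
    n_redrawn = n_redrawn
  ), class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that each strategy has
#' the highest net monetary benefit (`qaly * wtp - cost`) across draws.
#' Probabilities partition to 1 at every WTP point.
#'
#' @param draws Tibble with `draw`, `strategy`, `cost`, `qaly`.
#' @param wtp_grid Willingness-to-pay grid (CHF/QALY).
#' @return A tibble `wtp`, `strategy`, `probability`.
#' @export
ceac <- function(draws, wtp_grid) {
  strategies <- unique(draws$strategy)
  cost <- pivot_wider(draws, id_cols = "draw", names_from = "strategy",
                      values_from = "cost")
  qaly <- pivot_wider(draws, id_cols = "draw", names_from = "strategy",
                      values_from = "qaly")
  cm <- as.matrix(cost[strategies])
  qm <- as.matrix(qaly[strategies])
  out <- lapply(wtp_grid, function(w) {
    best <- max.col(qm * w - cm, ties.method = "first")
    tibble(wtp = w, strategy = strategies,
           probability = tabulate(best, ncol(cm)) / nrow(cm))
  })
  bind_rows(out)
}

#' @export
print.psa_result <- function(x, ...) {
  nd <- max(x$draws$draw)
  cat("<psa_result> ", nd, " draws, ", length(x$wtp_grid),
      " WTP points, seed ", x$seed, "\n", sep = "")
  wtp_ref <- x$wtp_grid[which.min(abs(x$wtp_grid - 1e5))]
  at_ref <- x$ceac[x$ceac$wtp == wtp_ref, ]
  cat("P(optimal) at WTP ", format(wtp_ref, big.mark = ","), ": ",
      paste(at_ref$strategy, sprintf("%.1f%%", 100 * at_ref$probability),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

scenario_labels <- function() {
  c("1" = "Low (generic) pemetrexed price",
    "2" = "Cross-over-adjusted chemo OS, no 2L pembrolizumab",
    "3" = "0% discount rate",
    "4" = "5% discount rate",
    "5" = "5-year time horizon",
    "6" = "Unlimited pemetrexed maintenance",
    "7" = "Time-on-treatment costing",
    "8" = "Lognormal OS for all strategies")
}

#' Apply a structural scenario to a configuration
#'
#' Returns a modified copy of the configuration (the input is never
#' mutated). The eight scenarios are: (1) pemetrexed at its generic price;
#' (2) the chemotherapy strategy's OS replaced by its cross-over-adjusted
#' curve with all progressors moving directly to BSC (no 2L pembrolizumab);
#' (3)/(4) discount rate 0% / 5%; (5) 5-year horizon (60 cycles);
#' (6) pemetrexed maintenance caps lifted (maintenance until progression or
#' death); (7) time-on-treatment costing of first-line drug/administration;
#' (8) lognormal OS for every strategy.
#'
#' @param config A validated `cea_config`.
#' @param scenario Scenario id in 1..8.
#' @return The modified `cea_config`.
#' @export
apply_scenario <- function(config, scenario) {
  if (!scenario %in% 1:8) {
    abort("scenario must be an id in 1..8.",
          class = "markovcea_config_error")
  }
  cfg <- config
  if (scenario == 1) {
    cfg$costs$unit_chf_per_month$pemetrexed <-
      cfg$costs$pemetrexed_generic_chf_per_month
  } else if (scenario == 2) {
    if (is.null(cfg$strategies$chemotherapy$os_crossover_adjusted)) {
      abort("Scenario 2 needs a cross-over-adjusted chemotherapy OS curve.",
            class = "markovcea_config_error")
    }
    cfg$strategies$chemotherapy$os <-
      cfg$strategies$chemotherapy$os_crossover_adjusted
    cfg$strategies$chemotherapy$p_second_line <- 0
  } else if (scenario == 3) {
    cfg$settings$discount_rate_annual <- 0
  } else if (scenario == 4) {
    cfg$settings$discount_rate_annual <- 0.05
  } else if (scenario == 5) {
    cfg$settings$horizon_cycles <- 60
  } else if (scenario == 6) {
    for (nm in names(cfg$strategies)) {
      for (line in c("first_line", "second_line")) {
        cfg$strategies[[nm]][[line]] <-
          lapply(cfg$strategies[[nm]][[line]], function(cm) {
            if (isTRUE(cm$maintenance_cap)) cm$to_month <- Inf
            cm
          })
      }
    }
  } else if (scenario == 7) {
    cfg$settings$tot_costing <- TRUE
  } else if (scenario == 8) {
    for (nm in names(cfg$strategies)) {
      if (is.null(cfg$strategies[[nm]]$os_alt_lognormal)) {
        abort(paste0("Scenario 8 needs a lognormal OS alternative for '",
                     nm, "'."), class = "markovcea_config_error")
      }
      cfg$strategies[[nm]]$os <- cfg$strategies[[nm]]$os_alt_lognormal
    }
  }
  cfg
}

#' Run the base case and the structural scenarios
#'
#' @param config A validated `cea_config`.
#' @param ids Scenario ids to run (default all eight).
#' @return A tibble with one row per scenario (id 0 = base case) and
#'   strategy: `scenario_id`, `scenario`, `strategy`, `total_cost_chf`,
#'   `qalys`, plus the two headline ICERs repeated per scenario
#'   (`icer_pembrolizumab_vs_chemotherapy`,
#'   `icer_combination_vs_pembrolizumab`).
#' @export
run_scenarios <- function(config, ids = 1:8) {
  one <- function(id) {
    cfg <- if (id == 0) config else apply_scenario(config, id)
    outs <- suppressWarnings(run_model(cfg))
    pair_icer <- function(a, b) {
      if (!all(c(a, b) %in% outs$strategy)) return(NA_real_)
      inc <- incrementals(outs, a, b)
      icer(inc$delta_total_cost_chf, inc$delta_qalys)$icer
    }
    outs |>
      select("strategy", "total_cost_chf", "qalys") |>
      mutate(
        scenario_id = id,
        scenario = if (id == 0) "Base case" else scenario_labels()[[as.character(id)]],
        icer_pembrolizumab_vs_chemotherapy =
          pair_icer("pembrolizumab", "chemotherapy"),
        icer_combination_vs_pembrolizumab =
          pair_icer("combination", "pembrolizumab"),
        .before = 1
      )
  }
  bind_rows(lapply(c(0, ids), one))
}
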