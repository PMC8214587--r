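#' Generate a complete synthetic model configuration
#'
#' Builds the full input set the cost-effectiveness pipeline needs: three
#' first-line strategies (chemotherapy, pembrolizumab monotherapy,
#' pembrolizumab + chemotherapy combination) with their fitted-curve
#' stand-ins, second-line structure, unit costs, adverse-event burden,
#' utilities, and run settings. The structure mirrors a Swiss payer
#' evaluation of these strategies: monthly cycles, 10-year horizon, 3%
#' annual discounting, CHF 100,000/QALY willingness-to-pay.
#'
#' Magnitudes are synthetic but realistic (the underlying published
#' analysis keeps its exact unit costs and fitted curve parameters in
#' supplementary material): overall survival is exponential and
#' progression-free survival lognormal per strategy, second-line treatment
#' runs until fixed progression times (4.2 months on 2L chemotherapy, 5.2
#' months on 2L pembrolizumab), induction chemotherapy lasts 4 cycles
#' (2.76 months), and pemetrexed maintenance is capped at 35 cycles.
#'
#' Costs and utilities are mildly jittered by `seed` (survival parameters are
#' fixed study conditions); the same seed yields a byte-identical serialized
#' configuration, and every generated configuration passes
#' [validate_config()].
#'
#' @param seed Integer seed controlling the cost/utility jitter.
#' @return A nested configuration list of class `cea_config`.
#' @examples
#' cfg <- generate_paramset(seed = 1)
#' names(cfg$strategies)
#' @export
generate_paramset <- function(seed = 1) {
  jit <- with_seed(seed, {
    list(
      cost = stats::rlnorm(9, 0, 0.05),
      u_pfs = runif(1, -0.02, 0.02),
      u_pd = runif(4, -0.02, 0.02)
    )
  })

  unit0 <- c(
    pembrolizumab = 10800, pemetrexed = 6000, carboplatin = 1500,
    paclitaxel = 1600, docetaxel = 2000, administration = 400,
    diagnostics = 500, bsc = 2000, end_of_life = 15000
  )
  unit <- round(unit0 * jit$cost, 2)

  u_pfs <- round(0.78 + jit$u_pfs, 4)
  u_pd0 <- c(pembrolizumab = 0.75, chemotherapy = 0.65, docetaxel = 0.64,
             bsc = 0.58)
  # PD utilities jittered but kept strictly below the 1L PFS utility
  u_pd <- round(pmin(u_pd0 + jit$u_pd, u_pfs - 0.03), 4)

  comp <- function(kind, cost_key, multiplier = 1, from_month = 0,
                   to_month = Inf, maintenance_cap = FALSE) {
    list(kind = kind, cost_key = cost_key, multiplier = multiplier,
         from_month = from_month, to_month = to_month,
         maintenance_cap = maintenance_cap)
  }
  induction_months <- 2.76              # 4 cycles of 3 weeks
  maintenance_cap_months <- induction_months + 35  # 35-cycle pemetrexed cap

  strategies <- list(
    chemotherapy = list(
      name = "chemotherapy",
      label = "Chemotherapy (platinum + pemetrexed)",
      os  = list(family = "exponential", params = list(rate = 0.045)),
      os_crossover_adjusted =
        list(family = "exponential", params = list(rate = 0.055)),
      os_alt_lognormal =
        list(family = "lognormal", params = list(meanlog = 2.73, sdlog = 1.1)),
      pfs = list(family = "lognormal", params = list(meanlog = 1.5, sdlog = 1.0)),
      tot = list(family = "lognormal", params = list(meanlog = 1.3, sdlog = 1.0)),
      p_second_line = 0.5,
      second_line_utility_key = "pembrolizumab",
      second_line_pfs_months = 5.2,
      first_line = list(
        carboplatin = comp("drug", "carboplatin", to_month = induction_months),
        pemetrexed = comp("drug", "pemetrexed",
                          to_month = maintenance_cap_months,
                          maintenance_cap = TRUE),
        administration = comp("admin", "administration"),
        diagnostics = comp("diagnostics", "diagnostics")
      ),
      second_line = list(
        pembrolizumab = comp("drug", "pembrolizumab"),
        administration = comp("admin", "administration")
      ),
      ae_incidence = list(pneumonitis = 0.01, anaemia = 0.20, colitis = 0.005,
                          exanthema_rash = 0.01, other_grade34 = 0.18),
      ae_cost_multiplier = 1
    ),
    pembrolizumab = list(
      name = "pembrolizumab",
      label = "Pembrolizumab monotherapy",
      os  = list(family = "exponential", params = list(rate = 0.0265)),
      os_alt_lognormal =
        list(family = "lognormal", params = list(meanlog = 3.26, sdlog = 1.1)),
      pfs = list(family = "lognormal", params = list(meanlog = 2.3, sdlog = 1.3)),
      tot = list(family = "lognormal", params = list(meanlog = 2.1, sdlog = 1.2)),
      p_second_line = 0.5,
      second_line_utility_key = "chemotherapy",
      second_line_pfs_months = 4.2,
      first_line = list(
        # pembrolizumab licence cap: up to 35 three-weekly cycles (~2 years)
        pembrolizumab = comp("drug", "pembrolizumab", to_month = 35),
        administration = comp("admin", "administration"),
        diagnostics = comp("diagnostics", "diagnostics")
      ),
      second_line = list(
        carboplatin = comp("drug", "carboplatin", to_month = induction_months),
        paclitaxel = comp("drug", "paclitaxel", multiplier = 0.5,
                          to_month = induction_months),
        pemetrexed_induction = comp("drug", "pemetrexed", multiplier = 0.5,
                                    to_month = induction_months),
        pemetrexed_maintenance = comp("drug", "pemetrexed", multiplier = 0.5,
                                      from_month = induction_months,
                                      to_month = maintenance_cap_months,
                                      maintenance_cap = TRUE),
        administration = comp("admin", "administration")
      ),
      ae_incidence = list(pneumonitis = 0.04, anaemia = 0.02, colitis = 0.015,
                          exanthema_rash = 0.02, other_grade34 = 0.10),
      ae_cost_multiplier = 1
    ),
    combination = list(
      name = "combination",
      label = "Pembrolizumab + chemotherapy",
      os  = list(family = "exponential", params = list(rate = 0.0235)),
      os_alt_lognormal =
        list(family = "lognormal", params = list(meanlog = 3.38, sdlog = 1.1)),
      pfs = list(family = "lognormal", params = list(meanlog = 2.45, sdlog = 1.3)),
      tot = list(family = "lognormal", params = list(meanlog = 2.2, sdlog = 1.2)),
      p_second_line = 0.45,
      second_line_utility_key = "docetaxel",
      second_line_pfs_months = 4.2,
      first_line = list(
        pembrolizumab = comp("drug", "pembrolizumab", to_month = 35),
        carboplatin = comp("drug", "carboplatin", to_month = induction_months),
        pemetrexed = comp("drug", "pemetrexed",
                          to_month = maintenance_cap_months,
                          maintenance_cap = TRUE),
        administration = comp("admin", "administration"),
        diagnostics = comp("diagnostics", "diagnostics")
      ),
      second_line = list(
        docetaxel = comp("drug", "docetaxel", to_month = induction_months),
        administration = comp("admin", "administration",
                              to_month = induction_months)
      ),
      ae_incidence = list(pneumonitis = 0.045, anaemia = 0.17, colitis = 0.02,
                          exanthema_rash = 0.02, other_grade34 = 0.25),
      ae_cost_multiplier = 1
    )
  )

  config <- structure(list(
    settings = list(
      cycle_length_months = 1,
      horizon_cycles = 120,
      discount_rate_annual = 0.03,
      half_cycle_correction = TRUE,
      tot_costing = FALSE,
      wtp_chf_per_qaly = 100000,
      seed = as.integer(seed)
    ),
    costs = list(
      unit_chf_per_month = as.list(unit[setdiff(names(unit), "end_of_life")]),
      end_of_life_chf = unname(unit[["end_of_life"]]),
      pemetrexed_generic_chf_per_month = round(unname(unit[["pemetrexed"]]) * 0.4, 2),
      ae_unit_chf = list(pneumonitis = 8000, anaemia = 3000, colitis = 7000,
                         exanthema_rash = 2000, other_grade34 = 4000)
    ),
    utilities = list(
      pfs_first_line = u_pfs,
      pd_second_line = as.list(u_pd[c("pembrolizumab", "chemotherapy",
                                      "docetaxel")]),
      bsc = unname(u_pd[["bsc"]])
    ),
    psa = list(
      n_draws = 10000,
      cost_cv = 0.2,
      utility_nu = 50,
      p_second_line_nu = 40,
      survival_log_se = 0.05,
      pfs_meanlog_se = 0.05,
      duration_cv = 0.1
    )
  ), class = "cea_config")
  config$strategies <- strategies
  validate_config(config)
  config
}

#' Validate a model configuration
#'
#' Checks every structural invariant downstream modules rely on: settings
#' ranges, survival families and parameter supports, nonnegative costs,
#' utilities in (0, 1] with the 1L PFS utility above all PD utilities,
#' second-line uptake probabilities in \[0, 1\], positive durations, and
#' (on the monthly evaluation grid) that each strategy's PFS survivor lies
#' below its OS survivor. A PFS/OS crossing is reported as a warning rather
#' than an error because independently fitted curves can cross and the
#' engine floors the resulting negative progression probabilities.
#'
#' @param config A `cea_config` list.
#' @return Invisibly `TRUE`; aborts with a descriptive error on violation.
#' @export
validate_config <- function(config) {
  fail <- function(msg) abort(msg, class = "markovcea_config_error")
  s <- config$settings
  if (is.null(s) || s$horizon_cycles < 1) fail("settings.horizon_cycles must be >= 1.")
  if (s$discount_rate_annual < 0) fail("settings.discount_rate_annual must be >= 0.")
  if (!identical(as.numeric(s$cycle_length_months), 1)) {
    fail("settings.cycle_length_months is fixed at 1 month.")
  }
  unit <- unlist(config$costs$unit_chf_per_month)
  if (any(unit < 0) || config$costs$end_of_life_chf < 0 ||
      any(unlist(config$costs$ae_unit_chf) < 0)) {
    fail("All costs must be >= 0 CHF.")
  }
  u <- c(config$utilities$pfs_first_line,
         unlist(config$utilities$pd_second_line), config$utilities$bsc)
  if (any(u <= 0) || any(u > 1)) fail("Utilities must lie in (0, 1].")
  if (any(unlist(config$utilities$pd_second_line) >=
          config$utilities$pfs_first_line)) {
    fail("PD utilities must be below the 1L PFS utility.")
  }
  if (length(config$strategies) < 1) fail("At least one strategy is required.")
  grid <- seq_len(s$horizon_cycles)
  for (st in config$strategies) {
    os <- parametric_survival(st$os$family, st$os$params)
    pfs <- parametric_survival(st$pfs$family, st$pfs$params)
    if (st$p_second_line < 0 || st$p_second_line > 1) {
      fail(paste0("p_second_line of '", st$name, "' must be in [0, 1]."))
    }
    if (st$second_line_pfs_months <= 0) {
      fail("second_line_pfs_months must be > 0.")
    }
    for (cm in c(st$first_line, st$second_line)) {
      if (cm$to_month <= cm$from_month) fail("Component durations must be > 0.")
      if (is.null(config$costs$unit_chf_per_month[[cm$cost_key]])) {
        fail(paste0("Unknown cost_key '", cm$cost_key, "'."))
      }
    }
    if (any(survivor(pfs, grid) > survivor(os, grid) + 1e-12)) {
      warn(paste0("Strategy '", st$name, "': PFS survivor exceeds OS on the ",
                  "monthly grid; progression probabilities will be floored."))
    }
  }
  invisible(TRUE)
}

#' Get or set a configuration value by dotted path
#'
#' Sensitivity analyses address parameters by paths such as
#' `"costs.unit_chf_per_month.pembrolizumab"` or
#' `"strategies.chemotherapy.os.params.rate"`.
#'
#' @param config A `cea_config` list.
#' @param path Dotted component path.
#' @param value Replacement value (for `config_set()`).
#' @return `config_get()` the value; `config_set()` the modified
#'   configuration (the input is never mutated).
#' @export
config_get <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  out <- purrr::pluck(config, !!!keys)
  if (is.null(out)) {
    abort(paste0("No configuration value at path '", path, "'."),
          class = "markovcea_config_error")
  }
  out
}

#' @rdname config_get
#' @export
config_set <- function(config, path, value) {
  config_get(config, path) # errors if absent
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  purrr::assign_in(config, keys, value)
}

#' Read and write configurations as YAML
#'
#' The on-disk format is a nested key-value text file with explicit units in
#' key names (`_chf_per_month`, `_months`, ...) so that unit mistakes are
#' visible at the configuration surface.
#'
#' @param config A `cea_config` list.
#' @param path File path.
#' @return `write_config()` the path invisibly; `read_config()` a validated
#'   `cea_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  config <- structure(yaml::read_yaml(path), class = "cea_config")
  validate_config(config)
  config
}

#' Serialize a configuration to a YAML string
#' @param config A `cea_config` list.
#' @return A single YAML string (stable for identical configurations).
#' @export
config_yaml <- function(config) yaml::as.yaml(unclass(config))

#' Run manifest
#'
#' Records what a reproducible run consisted of: a stable hash of the
#' configuration, the seeds used, the package version, output files and a
#' timestamp.
#'
#' @param config A `cea_config` list.
#' @param outputs Character vector of output file paths.
#' @param seeds Named or unnamed integer vector of seeds used.
#' @return A one-row tibble.
#' @export
run_manifest <- function(config, outputs = character(), seeds = integer()) {
  tibble(
    config_hash = rlang::hash(config_yaml(config)),
    seeds = paste(seeds, collapse = ","),
    package_version = as.character(utils::packageVersion("markovcea")),
    outputs = paste(outputs, collapse = ";"),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
}
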