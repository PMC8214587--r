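test_that("discount factors follow the midpoint convention", {
  expect_equal(discount_factor(0, 0:50), rep(1, 51))
  expect_equal(discount_factor(0.03, 12, half_cycle_correction = FALSE),
               1 / 1.03)
  expect_equal(discount_factor(0.03, 0), 1.03^(-0.5 / 12))
  f <- discount_factor(0.03, 0:119)
  expect_true(all(diff(f) < 0))
})

test_that("unit rewards make QALYs equal discounted life years", {
  cfg <- test_config()
  cfg$costs$unit_chf_per_month <- lapply(cfg$costs$unit_chf_per_month,
                                         function(x) 0)
  cfg$costs$end_of_life_chf <- 0
  cfg$utilities$pfs_first_line <- 1
  cfg$utilities$pd_second_line <- lapply(cfg$utilities$pd_second_line,
                                         function(x) 1)
  cfg$utilities$bsc <- 1
  for (nm in names(cfg$strategies)) {
    cfg$strategies[[nm]]$ae_incidence <-
      lapply(cfg$strategies[[nm]]$ae_incidence, function(x) 0)
  }
  out <- quiet_run_model(cfg)
  expect_equal(out$qalys, out$lys_discounted, tolerance = 1e-12)
  expect_equal(out$total_cost_chf, rep(0, 3))
})

test_that("an immortal cohort accrues no end-of-life cost", {
  cfg <- test_config()
  st <- cfg$strategies$chemotherapy
  probs <- tibble::tibble(cycle = 0:119, p_death = 0, p_pfs_to_pd = 0.02)
  trace <- markov_trace(probs, 120)
  out <- accrue(trace, cfg$costs, cfg$utilities, cfg$settings, st)
  expect_equal(out$cost_end_of_life_chf, 0)
  expect_equal(out$proportion_dead, 0)
  expect_equal(out$lys_undiscounted, 10)
})

test_that("accrual matches an independent spreadsheet-style recomputation", {
  cfg <- test_config()
  st <- cfg$strategies$chemotherapy
  horizon <- 3
  settings <- model_settings(horizon_cycles = horizon)
  trace <- run_cohort(st, settings)
  out <- accrue(trace, cfg$costs, cfg$utilities, settings, st)

  # independent recomputation with explicit arithmetic
  u <- cfg$costs$unit_chf_per_month
  ov <- function(m, a, b) max(0, min(b, m + 1) - max(a, m))
  p2l <- st$p_second_line
  tun <- attr(trace, "pd_tunnel")
  df <- (1.03)^(-(0:(horizon - 1) + 0.5) / 12)

  cost <- sum(unlist(st$ae_incidence) * unlist(cfg$costs$ae_unit_chf))
  qaly <- 0
  ly <- 0
  for (m in 0:(horizon - 1)) {
    f1 <- u$carboplatin * ov(m, 0, 2.76) + u$pemetrexed * ov(m, 0, 37.76) +
      u$administration + u$diagnostics
    pfs_occ <- (trace$pfs[m + 1] + trace$pfs[m + 2]) / 2
    cyc_cost <- f1 * pfs_occ
    cyc_q <- cfg$utilities$pfs_first_line * pfs_occ
    cyc_ly <- pfs_occ
    for (a in 0:(horizon - 1)) {
      occ <- (tun[m + 1, a + 1] + tun[m + 2, a + 1]) / 2
      active <- ov(a, 0, 5.2)
      s2 <- p2l * (u$pembrolizumab + u$administration) * active
      bsc <- u$bsc * ((1 - p2l) + p2l * ov(a, 5.2, Inf))
      u_pd <- p2l * (cfg$utilities$pd_second_line$pembrolizumab * active +
                       cfg$utilities$bsc * (1 - active)) +
        (1 - p2l) * cfg$utilities$bsc
      cyc_cost <- cyc_cost + (s2 + bsc) * occ
      cyc_q <- cyc_q + u_pd * occ
      cyc_ly <- cyc_ly + occ
    }
    cyc_cost <- cyc_cost + cfg$costs$end_of_life_chf * trace$new_deaths[m + 2]
    cost <- cost + df[m + 1] * cyc_cost
    qaly <- qaly + df[m + 1] * cyc_q
    ly <- ly + df[m + 1] * cyc_ly
  }
  expect_equal(out$total_cost_chf, cost, tolerance = 1e-10)
  expect_equal(out$qalys, qaly / 12, tolerance = 1e-10)
  expect_equal(out$lys_discounted, ly / 12, tolerance = 1e-10)
})

test_that("accounting identities hold across strategies", {
  cfg <- test_config()
  out <- quiet_run_model(cfg)
  categories <- out$cost_first_line_chf + out$cost_adverse_events_chf +
    out$cost_second_line_chf + out$cost_bsc_chf + out$cost_end_of_life_chf
  expect_equal(out$total_cost_chf, categories, tolerance = 1e-12)
  expect_true(all(out$qalys <= out$lys_discounted))
  expect_true(all(out$lys_discounted <= out$lys_undiscounted))
  expect_equal(out$months_in_pfs + out$months_in_pd,
               out$lys_undiscounted * 12, tolerance = 1e-8)
})

test_that("zero discounting reproduces undiscounted accumulation", {
  cfg <- test_config()
  cfg$settings$discount_rate_annual <- 0
  out <- quiet_run_model(cfg)
  expect_equal(out$lys_discounted, out$lys_undiscounted, tolerance = 1e-12)
})

test_that("every unit cost acts monotonically on total cost", {
  cfg <- test_config()
  base <- quiet_run_model(cfg)
  for (ck in names(cfg$costs$unit_chf_per_month)) {
    cfg2 <- config_set(cfg, paste0("costs.unit_chf_per_month.", ck),
                       cfg$costs$unit_chf_per_month[[ck]] * 1.1)
    up <- quiet_run_model(cfg2)
    expect_true(all(up$total_cost_chf >= base$total_cost_chf - 1e-9),
                label = paste("monotone in", ck))
  }
})

test_that("second-line cost profiles pro-rate fractional durations", {
  cfg <- test_config()
  combi <- cfg$strategies$combination
  prof <- second_line_cost_profile(combi, cfg$costs, horizon = 12)
  u <- cfg$costs$unit_chf_per_month
  p2l <- combi$p_second_line
  rate <- u$docetaxel + u$administration
  # docetaxel for 2.76 months: full cost in months 0-1, 76% in month 2, none after
  expect_equal(prof$second_line_chf[1:2], rep(p2l * rate, 2))
  expect_equal(prof$second_line_chf[3], p2l * rate * 0.76, tolerance = 1e-12)
  expect_equal(prof$second_line_chf[4], 0)
  # BSC starts for the 2L share after progression at 4.2 months
  expect_equal(prof$bsc_chf[5],
               u$bsc * ((1 - p2l) + p2l * 0.8), tolerance = 1e-12)
  expect_equal(prof$bsc_chf[6], u$bsc)

  # no second-line uptake: pure BSC from tunnel age zero
  none <- combi
  none$p_second_line <- 0
  prof0 <- second_line_cost_profile(none, cfg$costs, horizon = 12)
  expect_true(all(prof0$second_line_chf == 0))
  expect_equal(prof0$bsc_chf, rep(u$bsc, 12))
})
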