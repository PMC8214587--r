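owsa_fixture <- function() {
  cfg <- test_config()
  cfg$settings$horizon_cycles <- 60 # keep one-way sweeps quick
  cfg
}

test_that("the standard parameter set has 33 entries with valid bounds", {
  cfg <- test_config()
  pars <- owsa_parameters(cfg)
  expect_equal(nrow(pars), 33)
  expect_true(all(pars$low <= pars$central & pars$central <= pars$high))
  expect_true(all(pars$family %in%
                    c("normal", "normal_log", "gamma", "beta", "none")))
  # every path resolves
  for (p in pars$path) expect_silent(config_get(cfg, p))
})

test_that("one-way analysis: irrelevance, central identity and the two-point oracle", {
  cfg <- owsa_fixture()
  pars <- owsa_parameters(cfg)

  # a parameter of the chemo arm cannot move a combination-vs-pembrolizumab ICER
  chemo_os <- pars[pars$parameter == "OS rate (chemotherapy)", ]
  res <- owsa(cfg, chemo_os, "combination", "pembrolizumab")
  expect_equal(res$range_chf, 0)
  expect_equal(res$icer_low, attr(res, "base_icer"))

  # degenerate bounds at the central value reproduce the base-case ICER
  centered <- pars[1:3, ]
  centered$low <- centered$central
  centered$high <- centered$central
  res0 <- owsa(cfg, centered, "combination", "pembrolizumab")
  expect_equal(res0$icer_low, rep(attr(res0, "base_icer"), 3),
               tolerance = 1e-12)
  expect_equal(res0$icer_high, rep(attr(res0, "base_icer"), 3),
               tolerance = 1e-12)

  # two-point oracle: legs equal direct model reruns
  pem_cost <- pars[pars$path == "costs.unit_chf_per_month.pembrolizumab", ]
  pem_cost$low <- pem_cost$central * 0.8
  pem_cost$high <- pem_cost$central * 1.2
  res2 <- owsa(cfg, pem_cost, "combination", "pembrolizumab")
  direct <- function(value) {
    cfg2 <- config_set(cfg, pem_cost$path, value)
    outs <- suppressWarnings(dplyr::bind_rows(
      run_strategy(cfg2, "combination"), run_strategy(cfg2, "pembrolizumab")
    ))
    inc <- incrementals(outs, "combination", "pembrolizumab")
    inc$delta_total_cost_chf / inc$delta_qalys
  }
  expect_equal(res2$icer_low, direct(pem_cost$low), tolerance = 1e-12)
  expect_equal(res2$icer_high, direct(pem_cost$high), tolerance = 1e-12)

  # ranking is invariant to the order of the parameter list
  sub <- pars[c(2, 1, 11, 10), ]
  r1 <- owsa(cfg, sub, "combination", "pembrolizumab")
  r2 <- owsa(cfg, sub[c(3, 1, 4, 2), ], "combination", "pembrolizumab")
  expect_equal(r1$parameter[order(r1$rank)], r2$parameter[order(r2$rank)])
})

test_that("PSA draws are reproducible and CEAC probabilities partition", {
  cfg <- owsa_fixture()
  pars <- owsa_parameters(cfg)
  wtp <- seq(0, 200000, by = 50000)
  p1 <- psa(cfg, pars, n_draws = 1, wtp_grid = wtp, seed = 7)
  p2 <- psa(cfg, pars, n_draws = 1, wtp_grid = wtp, seed = 7)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$ceac, p2$ceac)

  p <- psa(cfg, pars, n_draws = 40, wtp_grid = wtp, seed = 8)
  sums <- p$ceac |>
    dplyr::summarise(s = sum(probability), .by = wtp)
  expect_equal(sums$s, rep(1, length(wtp)), tolerance = 1e-12)
  expect_true(all(p$ceac$probability >= 0 & p$ceac$probability <= 1))
})

test_that("degenerate-variance PSA collapses to the base case", {
  cfg <- owsa_fixture()
  pars <- owsa_parameters(cfg)
  pars$family <- "none" # zero-variance: every draw is the central value
  wtp <- c(0, 100000, 300000)
  p <- psa(cfg, pars, n_draws = 5, wtp_grid = wtp, seed = 9)
  base <- quiet_run_model(cfg)
  for (w in wtp) {
    nmb <- base$qalys * w - base$total_cost_chf
    best <- base$strategy[which.max(nmb)]
    step <- p$ceac[p$ceac$wtp == w, ]
    expect_equal(step$probability[step$strategy == best], 1)
  }
})

test_that("acceptance of a dearer, more effective strategy rises with WTP", {
  # direct CEAC on analytically constructed draws: pembro costs more and
  # yields more QALYs than chemo on average
  set.seed(11)
  n <- 2000
  draws <- dplyr::bind_rows(
    tibble::tibble(draw = 1:n, strategy = "chemotherapy",
                   cost = rnorm(n, 100000, 10000), qaly = rnorm(n, 1.0, 0.1)),
    tibble::tibble(draw = 1:n, strategy = "pembrolizumab",
                   cost = rnorm(n, 155000, 12000), qaly = rnorm(n, 1.9, 0.15))
  )
  cc <- ceac(draws, seq(0, 200000, by = 20000))
  p_pem <- cc$probability[cc$strategy == "pembrolizumab"]
  expect_true(all(diff(p_pem) >= -0.02)) # non-decreasing up to MC noise
})

test_that("scenario application is stateless and structurally correct", {
  cfg <- test_config()
  before <- config_yaml(cfg)

  s1 <- apply_scenario(cfg, 1)
  expect_equal(s1$costs$unit_chf_per_month$pemetrexed,
               cfg$costs$pemetrexed_generic_chf_per_month)

  s2 <- apply_scenario(cfg, 2)
  expect_equal(s2$strategies$chemotherapy$os,
               cfg$strategies$chemotherapy$os_crossover_adjusted)
  expect_equal(s2$strategies$chemotherapy$p_second_line, 0)

  expect_equal(apply_scenario(cfg, 3)$settings$discount_rate_annual, 0)
  expect_equal(apply_scenario(cfg, 4)$settings$discount_rate_annual, 0.05)
  expect_equal(apply_scenario(cfg, 5)$settings$horizon_cycles, 60)

  s6 <- apply_scenario(cfg, 6)
  expect_identical(
    s6$strategies$combination$first_line$pemetrexed$to_month, Inf)
  expect_identical(
    s6$strategies$pembrolizumab$second_line$pemetrexed_maintenance$to_month,
    Inf)
  # the licence cap on 1L pembrolizumab is not a maintenance cap
  expect_equal(s6$strategies$pembrolizumab$first_line$pembrolizumab$to_month,
               cfg$strategies$pembrolizumab$first_line$pembrolizumab$to_month)

  expect_true(apply_scenario(cfg, 7)$settings$tot_costing)
  s8 <- apply_scenario(cfg, 8)
  for (nm in names(s8$strategies)) {
    expect_equal(s8$strategies[[nm]]$os$family, "lognormal")
  }

  expect_error(apply_scenario(cfg, 9), class = "markovcea_config_error")
  # the input configuration was never mutated
  expect_identical(config_yaml(cfg), before)
})
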