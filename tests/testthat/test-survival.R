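test_that("survivor functions satisfy their defining identities", {
  models <- list(
    parametric_survival("exponential", c(rate = log(2) / 12)),
    parametric_survival("weibull", c(shape = 1.3, scale = 15)),
    parametric_survival("lognormal", c(meanlog = 2, sdlog = 0.9)),
    parametric_survival("loglogistic", c(shape = 1.5, scale = 12)),
    parametric_survival("gompertz", c(shape = 0.02, rate = 0.03))
  )
  grid <- seq(0, 240, by = 0.25)
  for (m in models) {
    expect_equal(survivor(m, 0), 1)
    s <- survivor(m, grid)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) <= 1e-12)) # monotone non-increasing
  }
  # median identities
  expect_equal(survivor(models[[1]], 12), 0.5)
  expect_equal(survivor(models[[3]], exp(2)), 0.5)
  expect_error(survivor(models[[1]], -1), class = "markovcea_domain_error")
  expect_error(parametric_survival("exponential", c(rate = 0)),
               class = "markovcea_domain_error")
  expect_error(parametric_survival("weibull", c(shape = 1)),
               class = "markovcea_config_error")
})

test_that("exponential MLE matches the events-over-exposure closed form", {
  ipd <- generate_ipd("exponential", c(rate = 0.06), n = 400,
                      censoring_time = 24, seed = 21)
  fit <- fit_parametric(ipd, "exponential")
  rate_closed <- sum(ipd$event) / sum(ipd$time)
  expect_equal(fit$model$params[["rate"]], rate_closed, tolerance = 1e-8)
  # information-criterion definitions, k = 1
  expect_equal(fit$aic, 2 - 2 * fit$loglik)
  expect_equal(fit$bic, log(nrow(ipd)) - 2 * fit$loglik)
  # closed-form variance of log-rate is 1/d
  expect_equal(unname(fit$covariance[1, 1]), 1 / sum(ipd$event),
               tolerance = 1e-3)
  expect_error(fit_parametric(dplyr::mutate(ipd, event = 0L), "exponential"),
               class = "markovcea_fit_error")
})

test_that("maximum-likelihood fits agree with an independent fitting engine", {
  ipd <- generate_ipd("weibull", c(shape = 1.4, scale = 18), n = 600,
                      censoring_time = 30, seed = 22)
  fit <- fit_parametric(ipd, "weibull")
  ref <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                               data = ipd, dist = "weibull")
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)
  expect_equal(unname(fit$model$params["shape"]),
               unname(ref$res["shape", "est"]), tolerance = 1e-4)
  expect_equal(unname(fit$model$params["scale"]),
               unname(ref$res["scale", "est"]), tolerance = 1e-4)

  lg <- generate_ipd("lognormal", c(meanlog = 2.1, sdlog = 0.7), n = 600,
                     censoring_time = 30, seed = 23)
  fit_ln <- fit_parametric(lg, "lognormal")
  ref_ln <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                                  data = lg, dist = "lnorm")
  expect_equal(fit_ln$loglik, ref_ln$loglik, tolerance = 1e-6)
})

test_that("tidy and glance expose fit results in broom shape", {
  ipd <- generate_ipd("exponential", c(rate = 0.05), n = 300,
                      censoring_time = 24, seed = 24)
  fit <- fit_parametric(ipd, "exponential")
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "transformed_term",
                     "transformed_estimate", "transformed_std_error"))
  gl <- glance(fit)
  expect_equal(gl$n, 300)
  expect_true(gl$s_120m >= 0 && gl$s_120m <= 1)
})

test_that("model selection minimizes the criterion with documented tie-breaks", {
  ipd <- generate_ipd("lognormal", c(meanlog = 1.5, sdlog = 0.8), n = 400,
                      censoring_time = 1e6, seed = 25)
  fits <- fit_candidates(ipd, c("exponential", "weibull", "lognormal"))
  best <- select_model(fits$fits, "aic")
  expect_equal(best$aic, min(fits$report$aic))
  # single candidate returned unchanged
  expect_identical(select_model(fits$fits["weibull"]), fits$fits$weibull)
  # exact criterion and parameter-count tie: first in fixed family order wins
  fake <- function(family, k) {
    structure(list(family = family, aic = 100, bic = 110,
                   theta = numeric(k)), class = "surv_fit")
  }
  tied <- list(fake("loglogistic", 2), fake("weibull", 2))
  expect_equal(select_model(tied, "aic")$family, "weibull")
  expect_error(select_model(list()), class = "markovcea_input_error")
})

test_that("the PH diagnostic behaves under null, identity and violation", {
  # identical samples: no hazard-ratio trend at all
  ipd <- generate_ipd("exponential", c(rate = 0.08), n = 300,
                      censoring_time = 24, seed = 26)
  same <- ph_diagnostic(ipd, ipd)
  expect_lt(same$statistic, 1e-6)
  expect_false(same$ph_rejected)

  # type-I error near the nominal 5% under the null
  rejections <- 0L
  for (r in 1:200) {
    a <- generate_ipd("exponential", c(rate = 0.1), n = 150,
                      censoring_time = 24, seed = 3000 + 2 * r)
    b <- generate_ipd("exponential", c(rate = 0.1), n = 150,
                      censoring_time = 24, seed = 3001 + 2 * r)
    if (ph_diagnostic(a, b)$ph_rejected) rejections <- rejections + 1L
  }
  expect_gte(rejections, 1L)
  expect_lte(rejections / 200, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))

  # power against a hazard that halves after month 6
  power_hits <- 0L
  for (r in 1:30) {
    a <- generate_ipd("exponential", c(rate = 0.15), n = 500,
                      censoring_time = 24, seed = 5000 + r)
    set.seed(6000 + r)
    tb <- rpiecewise_halving(500, 0.15)
    b <- tibble::tibble(time = pmin(tb, 24), event = as.integer(tb < 24))
    if (ph_diagnostic(a, b)$ph_rejected) power_hits <- power_hits + 1L
  }
  expect_gte(power_hits / 30, 0.8)
})

test_that("transition schedules implement the survivor-ratio formula", {
  lam <- 0.04
  exp_sched <- to_transition_schedule(
    parametric_survival("exponential", c(rate = lam)), 120
  )
  # constant-hazard signature: every cycle identical, equal to 1 - exp(-rate)
  expect_equal(exp_sched$tp, rep(1 - exp(-lam), 120), tolerance = 1e-12)

  ln <- parametric_survival("lognormal", c(meanlog = 2, sdlog = 0.9))
  sched <- to_transition_schedule(ln, 120)
  s <- stats::plnorm(0:120, 2, 0.9, lower.tail = FALSE)
  expect_equal(sched$tp, 1 - s[-1] / s[-121], tolerance = 1e-12)
  expect_true(all(sched$tp >= 0 & sched$tp <= 1))

  # near-degenerate S = 1: no transitions
  flat <- to_transition_schedule(
    parametric_survival("weibull", c(shape = 1, scale = 1e12)), 60
  )
  expect_true(all(flat$tp < 1e-10))

  # exhausted survivor: remaining probabilities forced to 1, with a note
  steep <- parametric_survival("exponential", c(rate = 50))
  expect_message(sched50 <- to_transition_schedule(steep, 60),
                 "set to 1")
  expect_true(all(sched50$tp[40:60 - 1] == 1))
})

test_that("fitted parameters converge to the truth as n grows", {
  bias <- sapply(c(200, 1000, 5000), function(n) {
    ipd <- generate_ipd("exponential", c(rate = 0.08), n = n,
                        censoring_time = 1e6, seed = 31)
    abs(fit_parametric(ipd, "exponential")$model$params[["rate"]] - 0.08)
  })
  expect_lt(bias[3], 0.08 * 0.05)
  expect_lt(bias[3], bias[1] + 0.08 * 0.02) # shrinking, allowing noise
})
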