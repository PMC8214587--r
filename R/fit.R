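#' Fit a parametric survival model to right-censored data
#'
#' Maximum-likelihood fit of one of the five candidate families to
#' individual-level `(time, event)` records under right censoring. The
#' likelihood is maximized on an unconstrained scale (log for positive
#' parameters), which is also the scale on which the parameter covariance is
#' reported — probabilistic sensitivity analysis draws survival parameters as
#' normals on this scale.
#'
#' @param ipd Data frame with `time` (months) and `event` (0/1) columns;
#'   at least two events are required.
#' @param family Survival family name (see [surv-families]).
#' @return An object of class `surv_fit`: the fitted [parametric_survival]
#'   model plus `loglik`, `aic`, `bic`, sample size `n`, `n_events`, the
#'   transformed-scale parameter vector `theta` and covariance matrix
#'   `covariance` (from the observed information).
#' @examples
#' ipd <- generate_ipd("exponential", c(rate = 0.08), 500, 24, seed = 2)
#' fit <- fit_parametric(ipd, "exponential")
#' glance(fit)
#' @export
fit_parametric <- function(ipd, family) {
  check_ipd(ipd)
  family <- check_family(family)
  d <- sum(ipd$event)
  if (d < 2) {
    abort("At least 2 observed events are required to fit.",
          class = "markovcea_fit_error")
  }
  t_ev <- ipd$time[ipd$event == 1]
  t_cn <- ipd$time[ipd$event == 0]
  if (any(t_ev <= 0)) {
    abort("Event times must be > 0 for parametric fitting.",
          class = "markovcea_fit_error")
  }

  negll <- function(theta) {
    m <- try(parametric_survival(family, par_untransform(family, theta)),
             silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    # NaNs from extreme trial parameters are handled as infeasible points
    ll <- suppressWarnings({
      v <- sum(surv_logdens(m, t_ev))
      if (length(t_cn)) v <- v + sum(log(pmax(survivor(m, t_cn), 1e-300)))
      v
    })
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  theta0 <- fit_start(family, t_ev, ipd$time)
  gr <- if (family == "exponential") {
    # d/dtheta of -loglik with theta = log(rate): total time at risk enters
    total_time <- sum(ipd$time)
    function(theta) -(d - exp(theta) * total_time)
  } else {
    NULL
  }

  opt <- optim(theta0, negll, gr = gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  if (length(theta0) > 1) {
    # Nelder-Mead restart guards against a bad BFGS path, then BFGS polish
    opt2 <- optim(opt$par, negll, method = "Nelder-Mead",
                  control = list(maxit = 2000, reltol = 1e-12))
    opt <- optim(opt2$par, negll, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-14))
  }
  if (opt$convergence != 0) {
    abort(paste0("Optimizer failed to converge for family '", family,
                 "' (code ", opt$convergence, ", message: ",
                 opt$message %||% "none", ")."),
          class = "markovcea_fit_error")
  }
  theta <- opt$par
  names(theta) <- transformed_names(family)
  k <- length(theta)
  hess <- stats::optimHess(theta, negll)
  covariance <- tryCatch({
    v <- solve(hess)
    (v + t(v)) / 2
  }, error = function(e) {
    warn("Observed information is singular; covariance set to NA.")
    matrix(NA_real_, k, k)
  })
  dimnames(covariance) <- list(names(theta), names(theta))

  loglik <- -opt$value
  structure(list(
    model = parametric_survival(family, par_untransform(family, theta)),
    family = family,
    loglik = loglik,
    aic = 2 * k - 2 * loglik,
    bic = k * log(nrow(ipd)) - 2 * loglik,
    n = nrow(ipd),
    n_events = d,
    theta = theta,
    covariance = covariance
  ), class = "surv_fit")
}

# crude moment-based starting values on the transformed scale
fit_start <- function(family, t_ev, t_all) {
  lt <- log(t_ev)
  m <- mean(lt); s <- max(stats::sd(lt), 0.2)
  switch(family,
    exponential = log(length(t_ev) / sum(t_all)),
    weibull     = c(log(1.2 / s), m),
    lognormal   = c(m, log(s)),
    loglogistic = c(log(1.2 / s), m),
    gompertz    = c(0.001, log(length(t_ev) / sum(t_all)))
  )
}

#' @export
print.surv_fit <- function(x, ...) {
  cat("<surv_fit> ", x$family, " | loglik ", signif(x$loglik, 7),
      " AIC ", signif(x$aic, 7), " BIC ", signif(x$bic, 7),
      " | n = ", x$n, " (", x$n_events, " events)\n", sep = "")
  print(x$model)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a parametric survival fit
#' @param x A `surv_fit`.
#' @param ... Unused.
#' @return One row per parameter: natural-scale `estimate`, the transformed
#'   (unconstrained) scale value and its standard error.
#' @method tidy surv_fit
#' @export
tidy.surv_fit <- function(x, ...) {
  tibble(
    term = names(x$model$params),
    estimate = unname(x$model$params),
    transformed_term = names(x$theta),
    transformed_estimate = unname(x$theta),
    transformed_std_error = sqrt(pmax(diag(x$covariance), 0))
  )
}

#' Glance at a parametric survival fit
#' @param x A `surv_fit`.
#' @param ... Unused.
#' @return One-row tibble with the family, log-likelihood, AIC, BIC, sample
#'   size and the extrapolated 10-year survivor `s_120m` (the long-term tail
#'   that visual inspection of candidate curves focuses on).
#' @method glance surv_fit
#' @export
glance.surv_fit <- function(x, ...) {
  tibble(
    family = x$family, loglik = x$loglik, aic = x$aic, bic = x$bic,
    n = x$n, n_events = x$n_events,
    s_120m = survivor(x$model, 120)
  )
}

#' Fit all candidate families and report
#'
#' Convenience wrapper fitting each candidate family to the same data and
#' returning a fit table (one [glance.surv_fit] row per family).
#'
#' @param ipd `(time, event)` records.
#' @param families Candidate families (default: all five).
#' @return A list with `fits` (named list of `surv_fit`) and `report`
#'   (tibble sorted by AIC).
#' @export
fit_candidates <- function(ipd, families = family_order()) {
  fits <- setNames(lapply(families, function(f) fit_parametric(ipd, f)),
                   families)
  report <- bind_rows(lapply(fits, glance)) |> arrange(.data$aic)
  list(fits = fits, report = report)
}

#' Select the best-fitting model by information criterion
#'
#' Picks the fit minimizing AIC (default) or BIC. Exact ties are broken by
#' fewer parameters, then by the fixed family order (exponential, weibull,
#' lognormal, loglogistic, gompertz).
#'
#' @param fits List of `surv_fit` objects on identical data.
#' @param criterion `"aic"` or `"bic"`.
#' @return The selected `surv_fit`.
#' @export
select_model <- function(fits, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  if (length(fits) == 0) {
    abort("select_model() needs at least one fit.",
          class = "markovcea_input_error")
  }
  crit <- map_dbl(fits, function(f) f[[criterion]])
  k <- map_dbl(fits, function(f) length(f$theta))
  fam_rank <- map_dbl(fits, function(f) match(f$family, family_order()))
  fits[[order(crit, k, fam_rank)[1]]]
}

#' Proportional-hazards diagnostic for two survival samples
#'
#' Tests the proportional-hazards assumption between two groups by the
#' Schoenfeld-residual score test of a log-time interaction on the group
#' hazard ratio ([survival::cox.zph()] with `transform = "log"`): a trend of
#' the hazard ratio over log time rejects PH. A rejected PH assumption is the
#' standard ground for modelling trial arms individually instead of pooling
#' them through a proportional-hazards comparison.
#'
#' @param ipd_a,ipd_b `(time, event)` records for the two groups (each with
#'   at least 2 events).
#' @param alpha Significance level for the decision (default 0.05).
#' @return One-row tibble: `statistic` (score chi-square), `df`, `p_value`,
#'   `ph_rejected`.
#' @export
ph_diagnostic <- function(ipd_a, ipd_b, alpha = 0.05) {
  check_ipd(ipd_a); check_ipd(ipd_b)
  if (sum(ipd_a$event) < 2 || sum(ipd_b$event) < 2) {
    abort("Both groups need >= 2 events for the PH diagnostic.",
          class = "markovcea_input_error")
  }
  dat <- bind_rows(
    mutate(ipd_a, group = 0L),
    mutate(ipd_b, group = 1L)
  )
  fit <- survival::coxph(survival::Surv(time, event) ~ group, data = dat)
  zp <- survival::cox.zph(fit, transform = "log")
  tibble(
    statistic = unname(zp$table["group", "chisq"]),
    df = unname(zp$table["group", "df"]),
    p_value = unname(zp$table["group", "p"]),
    ph_rejected = unname(zp$table["group", "p"]) < alpha
  )
}

#' Convert a survivor function into per-cycle transition probabilities
#'
#' The per-cycle exit probability for cycle `t` (spanning months `t` to
#' `t + 1`) is one minus the ratio of the survivor function at the end and
#' the beginning of the cycle: \eqn{tp_t = 1 - S(t+1)/S(t)}. Once the
#' survivor function reaches zero the remaining probabilities are set to 1
#' (with a note).
#'
#' @param model A [parametric_survival] object.
#' @param horizon_cycles Number of monthly cycles (>= 1).
#' @return A tibble with columns `cycle` (0-based) and `tp`, all in `[0, 1]`.
#' @export
to_transition_schedule <- function(model, horizon_cycles) {
  stopifnot(inherits(model, "parametric_survival"))
  if (horizon_cycles < 1) {
    abort("horizon_cycles must be >= 1.", class = "markovcea_config_error")
  }
  s <- survivor(model, 0:horizon_cycles)
  tp <- 1 - s[-1] / s[-length(s)]
  exhausted <- s[-length(s)] <= 0
  if (any(exhausted)) {
    inform(paste0("Survivor function reached 0 at cycle ",
                  which(exhausted)[1] - 1,
                  "; remaining transition probabilities set to 1."))
    tp[exhausted] <- 1
  }
  tibble(cycle = 0:(horizon_cycles - 1), tp = pmin(pmax(tp, 0), 1))
}
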