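#' Parametric survival families
#'
#' The package supports five parametric time-to-event families, the candidate
#' set conventionally screened in health-technology-assessment survival
#' extrapolation: exponential, Weibull, lognormal, log-logistic and Gompertz.
#' Time is measured in months throughout.
#'
#' Parameterizations follow the base-R / flexsurv conventions:
#' * `exponential`: `rate` (events per month), \eqn{S(t) = e^{-\lambda t}}
#' * `weibull`: `shape`, `scale`, \eqn{S(t) = e^{-(t/\sigma)^k}}
#' * `lognormal`: `meanlog`, `sdlog` on natural-log time
#' * `loglogistic`: `shape`, `scale`, \eqn{S(t) = 1/(1 + (t/\sigma)^k)}
#' * `gompertz`: `shape` (any real), `rate` (> 0)
#'
#' @name surv-families
NULL

# family registry: parameter names, which parameters must be positive, and the
# fixed order used for model-selection tie-breaks
surv_families <- function() {
  list(
    exponential = list(pars = "rate",                positive = "rate"),
    weibull     = list(pars = c("shape", "scale"),   positive = c("shape", "scale")),
    lognormal   = list(pars = c("meanlog", "sdlog"), positive = "sdlog"),
    loglogistic = list(pars = c("shape", "scale"),   positive = c("shape", "scale")),
    gompertz    = list(pars = c("shape", "rate"),    positive = "rate")
  )
}

family_order <- function() names(surv_families())

check_family <- function(family) {
  if (!is.character(family) || length(family) != 1 ||
      !family %in% family_order()) {
    abort(paste0(
      "Unknown survival family '", paste(family, collapse = ","),
      "'. Supported: ", paste(family_order(), collapse = ", "), "."
    ), class = "markovcea_config_error")
  }
  family
}

#' Construct a parametric survival model
#'
#' @param family One of `"exponential"`, `"weibull"`, `"lognormal"`,
#'   `"loglogistic"`, `"gompertz"`.
#' @param params Named numeric vector or list of the family's parameters
#'   (see [surv-families]).
#' @return An object of class `parametric_survival`.
#' @examples
#' m <- parametric_survival("exponential", c(rate = log(2) / 12))
#' survivor(m, 12) # 0.5: median at 12 months
#' @export
parametric_survival <- function(family, params) {
  family <- check_family(family)
  spec <- surv_families()[[family]]
  params <- unlist(params)
  if (!setequal(names(params), spec$pars)) {
    abort(paste0(
      "Family '", family, "' needs parameters {",
      paste(spec$pars, collapse = ", "), "}, got {",
      paste(names(params), collapse = ", "), "}."
    ), class = "markovcea_config_error")
  }
  params <- params[spec$pars]
  bad <- spec$positive[params[spec$positive] <= 0]
  if (length(bad)) {
    abort(paste0(
      "Parameter(s) ", paste(bad, collapse = ", "), " of family '", family,
      "' must be > 0."
    ), class = "markovcea_domain_error")
  }
  if (any(!is.finite(params))) {
    abort("Survival parameters must be finite.",
          class = "markovcea_domain_error")
  }
  structure(list(family = family, params = params),
            class = "parametric_survival")
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat("<parametric_survival> ", x$family, ": ",
      paste(names(x$params), signif(x$params, 5), sep = " = ",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Survivor function of a parametric model
#'
#' Evaluates \eqn{S(t)}, the probability of remaining event-free at `t` months.
#'
#' @param model A [parametric_survival] object.
#' @param t Vector of nonnegative times in months.
#' @return Numeric vector of survival probabilities in `[0, 1]`.
#' @export
survivor <- function(model, t) {
  stopifnot(inherits(model, "parametric_survival"))
  if (any(t < 0)) {
    abort("survivor() requires t >= 0.", class = "markovcea_domain_error")
  }
  p <- model$params
  switch(model$family,
    exponential = pexp(t, rate = p[["rate"]], lower.tail = FALSE),
    weibull     = pweibull(t, shape = p[["shape"]], scale = p[["scale"]],
                           lower.tail = FALSE),
    lognormal   = plnorm(t, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]],
                         lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p[["shape"]],
                                    scale = p[["scale"]], lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, shape = p[["shape"]],
                                      rate = p[["rate"]], lower.tail = FALSE)
  )
}

# log density, used by the censored likelihood
surv_logdens <- function(model, t) {
  p <- model$params
  switch(model$family,
    exponential = dexp(t, rate = p[["rate"]], log = TRUE),
    weibull     = dweibull(t, shape = p[["shape"]], scale = p[["scale"]],
                           log = TRUE),
    lognormal   = dlnorm(t, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]],
                         log = TRUE),
    loglogistic = flexsurv::dllogis(t, shape = p[["shape"]],
                                    scale = p[["scale"]], log = TRUE),
    gompertz    = flexsurv::dgompertz(t, shape = p[["shape"]],
                                      rate = p[["rate"]], log = TRUE)
  )
}

# random event times for the synthetic-data generator
surv_rng <- function(family, params, n) {
  p <- unlist(params)
  switch(family,
    exponential = stats::rexp(n, rate = p[["rate"]]),
    weibull     = stats::rweibull(n, shape = p[["shape"]], scale = p[["scale"]]),
    lognormal   = stats::rlnorm(n, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]]),
    loglogistic = flexsurv::rllogis(n, shape = p[["shape"]], scale = p[["scale"]]),
    gompertz    = flexsurv::rgompertz(n, shape = p[["shape"]], rate = p[["rate"]])
  )
}

# unconstrained <-> natural parameter transforms (normal-scale PSA draws and
# unconstrained optimization both live on the transformed scale)
par_transform <- function(family, params) {
  spec <- surv_families()[[family]]
  th <- unlist(params)[spec$pars]
  th[spec$positive] <- log(th[spec$positive])
  names(th) <- transformed_names(family)
  th
}

par_untransform <- function(family, theta) {
  spec <- surv_families()[[family]]
  th <- unname(theta)
  names(th) <- spec$pars
  th[spec$positive] <- exp(th[spec$positive])
  th
}

transformed_names <- function(family) {
  spec <- surv_families()[[family]]
  ifelse(spec$pars %in% spec$positive, paste0("log_", spec$pars), spec$pars)
}
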