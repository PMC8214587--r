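#' Generate synthetic individual patient survival data
#'
#' Draws `n` event times from a parametric family and applies administrative
#' censoring at a fixed follow-up time, emulating trial follow-up (the
#' registration trials behind the default configuration had roughly 2 years
#' of follow-up). Random dropout is not modelled.
#'
#' @param family Survival family name (see [surv-families]).
#' @param params Named parameters for the family.
#' @param n Number of patients (>= 1).
#' @param censoring_time Administrative censoring time in months (> 0).
#' @param seed Integer seed; the same seed reproduces the same records.
#' @return A tibble with columns `time` (months, capped at `censoring_time`)
#'   and `event` (1 = observed, 0 = censored at cutoff).
#' @examples
#' ipd <- generate_ipd("exponential", c(rate = 0.05), n = 100,
#'                     censoring_time = 24, seed = 1)
#' mean(ipd$event) # close to 1 - exp(-0.05 * 24)
#' @export
generate_ipd <- function(family, params, n, censoring_time, seed) {
  family <- check_family(family)
  # constructor validates parameter names/positivity
  parametric_survival(family, params)
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("n must be a single count >= 1.", class = "markovcea_config_error")
  }
  if (!is.numeric(censoring_time) || censoring_time <= 0) {
    abort("censoring_time must be > 0.", class = "markovcea_config_error")
  }
  raw <- with_seed(seed, surv_rng(family, params, as.integer(n)))
  tibble(
    time  = pmin(raw, censoring_time),
    event = as.integer(raw < censoring_time)
  )
}

# scoped RNG so no global seed state leaks out
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Kaplan-Meier estimate on a time grid
#'
#' Thin wrapper around [survival::survfit()] evaluating the KM step function
#' at requested times (carrying the last value forward beyond follow-up).
#'
#' @param ipd Data frame with `time` and `event` columns.
#' @param times Evaluation times in months.
#' @return A tibble with columns `time` and `surv`.
#' @export
km_estimate <- function(ipd, times) {
  check_ipd(ipd)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd,
                           conf.type = "log-log")
  s <- summary(fit, times = times, extend = TRUE)
  tibble(time = s$time, surv = s$surv)
}

check_ipd <- function(ipd) {
  if (!is.data.frame(ipd) || !all(c("time", "event") %in% names(ipd)) ||
      nrow(ipd) == 0) {
    abort("ipd must be a non-empty data frame with columns time, event.",
          class = "markovcea_input_error")
  }
  if (any(ipd$time < 0) || !all(ipd$event %in% c(0, 1))) {
    abort("ipd requires time >= 0 and event in {0, 1}.",
          class = "markovcea_input_error")
  }
  invisible(ipd)
}

#' Emulate a digitized Kaplan-Meier curve
#'
#' Produces what curve digitization of a published KM figure would yield: the
#' KM estimate sampled on a coordinate grid, optionally perturbed by small
#' truncated-normal noise on the probability scale and then re-monotonized
#' (published curves are non-increasing, and digitization error must be
#' projected back onto that constraint before fitting), together with a
#' number-at-risk table at the figure's risk-table times.
#'
#' @param ipd Data frame of `time`/`event` records.
#' @param grid Strictly increasing coordinate times (months).
#' @param risk_times Times at which the number at risk is tabulated.
#' @param jitter_sd Standard deviation of digitization noise on the
#'   probability scale (0 = exact sampling of the KM step function).
#' @param seed Seed for the jitter.
#' @param endpoint_label `"OS"` or `"PFS"` tag carried on the result.
#' @return A list of class `digitized_curve` with tibbles `coordinates`
#'   (`time`, `surv`) and `risk_table` (`time`, `n_risk`), plus
#'   `endpoint_label`.
#' @export
emulate_digitized_curve <- function(ipd, grid, risk_times, jitter_sd = 0,
                                    seed = 1, endpoint_label = "OS") {
  check_ipd(ipd)
  if (length(grid) == 0 || any(diff(grid) <= 0)) {
    abort("grid must be strictly increasing.",
          class = "markovcea_input_error")
  }
  if (jitter_sd < 0) {
    abort("jitter_sd must be >= 0.", class = "markovcea_input_error")
  }
  km <- km_estimate(ipd, grid)
  surv <- km$surv
  if (jitter_sd > 0) {
    noise <- with_seed(seed, rnorm(length(surv), sd = jitter_sd))
    # truncate to +-2.5 sd: a digitizer does not misread a curve by much
    noise <- pmin(pmax(noise, -2.5 * jitter_sd), 2.5 * jitter_sd)
    surv <- pmin(pmax(surv + noise, 0), 1)
    # isotonic projection back to a non-increasing curve
    surv <- -stats::isoreg(grid, -surv)$yf
    if (grid[1] == 0) surv[1] <- 1
    surv <- pmin(pmax(surv, 0), 1)
  }
  structure(
    list(
      coordinates = tibble(time = grid, surv = surv),
      risk_table = tibble(
        time = risk_times,
        n_risk = vapply(risk_times, function(tt) sum(ipd$time >= tt),
                        integer(1))
      ),
      endpoint_label = match.arg(endpoint_label, c("OS", "PFS"))
    ),
    class = "digitized_curve"
  )
}

#' @export
print.digitized_curve <- function(x, ...) {
  cat("<digitized_curve> ", x$endpoint_label, ": ",
      nrow(x$coordinates), " coordinates, ",
      nrow(x$risk_table), " risk-table rows\n", sep = "")
  invisible(x)
}

validate_digitized_curve <- function(curve) {
  if (!inherits(curve, "digitized_curve") || nrow(curve$coordinates) == 0) {
    abort("Not a valid digitized_curve (empty coordinates?).",
          class = "markovcea_input_error")
  }
  s <- curve$coordinates$surv
  if (s[1] > 1 + 1e-12 || any(s < -1e-12) || any(diff(s) > 1e-12)) {
    abort("Digitized coordinates must be in [0, 1] and non-increasing.",
          class = "markovcea_input_error")
  }
  if (nrow(curve$risk_table) > 0 && any(diff(curve$risk_table$n_risk) > 0)) {
    abort("Risk-table counts must be non-increasing.",
          class = "markovcea_input_error")
  }
  invisible(curve)
}

#' Read/write survival data and digitized curves as delimited text
#'
#' IPD is stored as two-column CSV (`time,event`); a digitized curve as a
#' `time,surv` CSV plus a separate `time,n_risk` CSV.
#'
#' @param ipd,curve Objects to write.
#' @param path,coord_path,risk_path File paths.
#' @param endpoint_label Label restored on read.
#' @name synthetic-io
NULL

#' @rdname synthetic-io
#' @export
write_ipd <- function(ipd, path) {
  check_ipd(ipd)
  utils::write.csv(ipd[c("time", "event")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic-io
#' @export
read_ipd <- function(path) {
  dat <- utils::read.csv(path)
  check_ipd(dat)
  as_tibble(dat[c("time", "event")])
}

#' @rdname synthetic-io
#' @export
write_digitized_curve <- function(curve, coord_path, risk_path) {
  validate_digitized_curve(curve)
  utils::write.csv(curve$coordinates, coord_path, row.names = FALSE)
  utils::write.csv(curve$risk_table, risk_path, row.names = FALSE)
  invisible(coord_path)
}

#' @rdname synthetic-io
#' @export
read_digitized_curve <- function(coord_path, risk_path,
                                 endpoint_label = "OS") {
  out <- structure(
    list(
      coordinates = as_tibble(utils::read.csv(coord_path)),
      risk_table = as_tibble(utils::read.csv(risk_path)),
      endpoint_label = endpoint_label
    ),
    class = "digitized_curve"
  )
  validate_digitized_curve(out)
}
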