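#' Reconstruct pseudo individual patient data from a digitized curve
#'
#' Recovers approximate `(time, event)` records from digitized Kaplan-Meier
#' coordinates and a numbers-at-risk table, in the spirit of standard
#' KM-reconstruction algorithms: within each risk-table interval, events are
#' allocated at coordinate times so that the reconstructed KM estimate
#' reproduces the digitized survival drops, and censorings are allocated at
#' risk-table times to reconcile the running at-risk count with the published
#' counts. Any cohort remaining after the last coordinate is administratively
#' censored there.
#'
#' Events occurring between coordinate times are lumped at the next
#' coordinate, so the reconstruction is exact at the coordinate grid (and,
#' for curves digitized from trials with purely administrative censoring,
#' event/censor counts per interval are exact as well).
#'
#' @param curve A `digitized_curve` (see [emulate_digitized_curve()]).
#' @return A tibble of pseudo-IPD `time`/`event` records whose KM estimate
#'   matches the input coordinates.
#' @export
reconstruct_ipd <- function(curve) {
  validate_digitized_curve(curve)
  if (nrow(curve$risk_table) == 0) {
    abort("reconstruct_ipd() needs a non-empty risk table.",
          class = "markovcea_reconstruction_error")
  }
  co <- arrange(curve$coordinates, time)
  rt <- arrange(curve$risk_table, time)

  times <- numeric(0)
  events <- integer(0)
  emit <- function(t, e, count) {
    if (count > 0) {
      times <<- c(times, rep(t, count))
      events <<- c(events, rep(e, count))
    }
  }

  r <- rt$n_risk[1]       # at risk at the first risk-table time
  s_recon <- 1            # reconstructed KM value so far
  i <- 1                  # coordinate pointer

  process_coord <- function(i) {
    s_i <- co$surv[i]
    if (s_recon <= 0) {
      if (s_i > 1e-9) {
        abort("Coordinates rise above an exhausted survivor function.",
              class = "markovcea_reconstruction_error")
      }
      return(invisible())
    }
    d <- round(r * (1 - s_i / s_recon))
    d <- max(0L, min(as.integer(d), as.integer(r)))
    if (d > 0) {
      emit(co$time[i], 1L, d)
      s_recon <<- s_recon * (1 - d / r)
      r <<- r - d
    }
    invisible()
  }

  for (k in seq_len(nrow(rt))) {
    while (i <= nrow(co) && co$time[i] <= rt$time[k]) {
      process_coord(i)
      i <- i + 1
    }
    if (k > 1) {
      cens <- r - rt$n_risk[k]
      if (cens < -0.5) {
        abort(paste0(
          "Risk table inconsistent with coordinates at t = ", rt$time[k],
          ": ", rt$n_risk[k], " at risk but only ", r, " remain."
        ), class = "markovcea_reconstruction_error")
      }
      cens <- max(0L, as.integer(round(cens)))
      emit(rt$time[k], 0L, cens)
      r <- r - cens
    }
  }
  while (i <= nrow(co)) {
    process_coord(i)
    i <- i + 1
  }
  # administrative censoring of everyone still at risk at end of follow-up
  emit(co$time[nrow(co)], 0L, r)

  arrange(tibble(time = times, event = events), time, desc(event))
}
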