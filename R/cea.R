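#' Incremental outcomes between two strategies
#'
#' Componentwise differences (strategy minus comparator) of every numeric
#' outcome column present in the outcome table. Exact arithmetic, no
#' tolerance — printed totals transcribed into an outcome table reproduce
#' printed incrementals exactly.
#'
#' @param outcomes A data frame with one row per strategy (must contain a
#'   `strategy` column; typically a [run_model()] result or a transcribed
#'   results table).
#' @param strategy,comparator Strategy names to difference.
#' @return A one-row tibble with `strategy`, `comparator` and a
#'   `delta_<column>` for every numeric column.
#' @export
incrementals <- function(outcomes, strategy, comparator) {
  a <- outcomes[outcomes$strategy == strategy, , drop = FALSE]
  b <- outcomes[outcomes$strategy == comparator, , drop = FALSE]
  if (nrow(a) != 1 || nrow(b) != 1) {
    abort("strategy and comparator must each match exactly one outcome row.",
          class = "markovcea_input_error")
  }
  num <- names(outcomes)[vapply(outcomes, is.numeric, logical(1))]
  delta <- as_tibble(as.list(unlist(a[num]) - unlist(b[num])))
  names(delta) <- paste0("delta_", num)
  bind_cols(tibble(strategy = strategy, comparator = comparator), delta)
}

#' Incremental cost-effectiveness ratio with dominance mapping
#'
#' Maps every cost-effect quadrant to a ratio or a flag: a positive QALY
#' difference yields `delta_cost / delta_qaly`; more QALYs at lower cost is
#' `"dominant"`; fewer QALYs at higher cost is `"dominated"`; a zero QALY
#' difference is flagged `"no_qaly_difference"` (ICER undefined). Vectorized.
#'
#' @param delta_cost,delta_qaly Incremental cost (CHF) and QALYs.
#' @return A tibble with `icer` (CHF/QALY, `NA` when flagged) and
#'   `dominance` (`"none"`, `"dominant"`, `"dominated"`,
#'   `"no_qaly_difference"`).
#' @examples
#' icer(50000, 0.5)    # 100,000 CHF/QALY
#' icer(1000, -0.1)    # dominated
#' @export
icer <- function(delta_cost, delta_qaly) {
  n <- max(length(delta_cost), length(delta_qaly))
  delta_cost <- rep_len(delta_cost, n)
  delta_qaly <- rep_len(delta_qaly, n)
  dominance <- dplyr::case_when(
    delta_qaly > 0 & delta_cost < 0 ~ "dominant",
    delta_qaly < 0 & delta_cost >= 0 ~ "dominated",
    delta_qaly == 0 ~ "no_qaly_difference",
    .default = "none"
  )
  ratio <- ifelse(delta_qaly != 0, delta_cost / delta_qaly, NA_real_)
  # a ratio is only reported on the interpretable quadrants
  ratio[!dominance %in% c("none", "dominant")] <- NA_real_
  tibble(icer = ratio, dominance = dominance)
}

#' Pairwise cost-effectiveness comparisons
#'
#' Computes incremental costs, QALYs and life years, the ICER (CHF per QALY
#' gained) and cost per life year gained for each requested strategy pair.
#' The default pairs follow the conventional reporting of a three-strategy
#' evaluation: pembrolizumab vs chemotherapy, combination vs pembrolizumab,
#' and combination vs chemotherapy for completeness. ICERs are computed from
#' unrounded outcome values; round only at presentation.
#'
#' @param outcomes A [run_model()] outcome table.
#' @param comparisons A list of `c(strategy, comparator)` pairs; defaults to
#'   each strategy against its predecessor in table order plus the last
#'   against the first.
#' @return A `cea_result` tibble: one row per comparison with
#'   `delta_cost_chf`, `delta_qaly`, `delta_ly`, `icer_chf_per_qaly`,
#'   `cost_per_ly_chf`, `dominance`.
#' @export
cea <- function(outcomes, comparisons = NULL) {
  if (is.null(comparisons)) {
    nm <- outcomes$strategy
    comparisons <- c(
      lapply(seq_along(nm)[-1], function(i) c(nm[i], nm[i - 1])),
      if (length(nm) > 2) list(c(nm[length(nm)], nm[1]))
    )
  }
  rows <- lapply(comparisons, function(pair) {
    inc <- incrementals(outcomes, pair[1], pair[2])
    dc <- inc$delta_total_cost_chf %||% inc$delta_cost_chf
    dq <- inc$delta_qalys
    dl <- inc$delta_lys_discounted %||% NA_real_
    ic <- icer(dc, dq)
    tibble(
      strategy = pair[1], comparator = pair[2],
      delta_cost_chf = dc, delta_qaly = dq, delta_ly = dl,
      icer_chf_per_qaly = ic$icer,
      cost_per_ly_chf = ifelse(!is.na(dl) & dl > 0, dc / dl, NA_real_),
      dominance = ic$dominance
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("cea_result", class(out))
  out
}

#' Cost-effectiveness frontier
#'
#' Sorts strategies by cost, removes strictly dominated strategies (another
#' strategy is cheaper and at least as effective) and extendedly dominated
#' ones (a sequential ICER that decreases along the cost-ordered frontier),
#' and reports the sequential ICERs, which are strictly increasing along the
#' frontier.
#'
#' @param outcomes A [run_model()] outcome table (needs `strategy`,
#'   `total_cost_chf`, `qalys`).
#' @return A tibble of frontier strategies in increasing cost order with
#'   `sequential_icer_chf_per_qaly` (`NA` for the cheapest).
#' @export
frontier <- function(outcomes) {
  if (nrow(outcomes) < 2) {
    abort("frontier() needs at least 2 strategies.",
          class = "markovcea_input_error")
  }
  pts <- outcomes |>
    select("strategy", cost = "total_cost_chf", qaly = "qalys") |>
    arrange(.data$cost, .data$qaly)
  # strict dominance: drop any strategy with a cheaper-or-equal, at least as
  # effective alternative (other than itself)
  keep <- vapply(seq_len(nrow(pts)), function(i) {
    !any(pts$cost <= pts$cost[i] & pts$qaly >= pts$qaly[i] &
           seq_len(nrow(pts)) != i &
           (pts$cost < pts$cost[i] | pts$qaly > pts$qaly[i]))
  }, logical(1))
  pts <- pts[keep, , drop = FALSE]
  # extended dominance: enforce increasing sequential ICERs
  repeat {
    if (nrow(pts) < 3) break
    seq_icer <- diff(pts$cost) / diff(pts$qaly)
    drop_idx <- which(diff(seq_icer) < 0)
    if (length(drop_idx) == 0) break
    pts <- pts[-(drop_idx[1] + 1), , drop = FALSE]
  }
  pts$sequential_icer_chf_per_qaly <-
    c(NA_real_, diff(pts$cost) / diff(pts$qaly))
  rename(pts, total_cost_chf = "cost", qalys = "qaly")
}

#' Tidy a cea_result
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return The comparisons in long form (one row per comparison and metric).
#' @method tidy cea_result
#' @export
tidy.cea_result <- function(x, ...) {
  x |>
    as_tibble() |>
    pivot_longer(
      cols = c("delta_cost_chf", "delta_qaly", "delta_ly",
               "icer_chf_per_qaly", "cost_per_ly_chf"),
      names_to = "metric", values_to = "value"
    )
}

#' Glance at a cea_result
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return One row: number of comparisons, the ICER range, and how many
#'   comparisons carry a dominance flag.
#' @method glance cea_result
#' @export
glance.cea_result <- function(x, ...) {
  tibble(
    n_comparisons = nrow(x),
    min_icer = suppressWarnings(min(x$icer_chf_per_qaly, na.rm = TRUE)),
    max_icer = suppressWarnings(max(x$icer_chf_per_qaly, na.rm = TRUE)),
    n_dominance_flags = sum(x$dominance != "none")
  )
}
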