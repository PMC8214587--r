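# shared fixtures: all built in code at test time

test_config <- function(seed = 101) generate_paramset(seed)

# published Swiss base-case totals for the three first-line strategies,
# transcribed as printed (discounted unless stated otherwise)
base_case_table <- function() {
  path <- system.file("extdata", "table1_base_case.csv",
                      package = "markovcea")
  tibble::as_tibble(utils::read.csv(path))
}

# piecewise-exponential sampler whose hazard halves after `break_month`:
# a deliberate proportional-hazards violation for power checks
rpiecewise_halving <- function(n, rate, break_month = 6) {
  t1 <- stats::rexp(n, rate)
  late <- t1 > break_month
  t1[late] <- break_month + stats::rexp(sum(late), rate / 2)
  t1
}

quiet_run_model <- function(config) suppressWarnings(run_model(config))
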