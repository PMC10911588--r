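#' Cost-effectiveness run configuration
#'
#' Bundles everything one deterministic model run needs: the run settings,
#' the parameter table, the survival models per arm, the reference patient
#' and the willingness-to-pay threshold. The intervention arm is listed
#' first.
#'
#' @param table Parameter table (see [read_parameter_table()]).
#' @param spec A [psm_spec()].
#' @param arms Character vector of two arm labels, intervention first.
#' @param pat A [patient()].
#' @param wtp Willingness-to-pay threshold in USD/QALY (3x Chinese
#'   per-capita GDP, 2022).
#' @export
cea_config <- function(table, spec = psm_spec(),
                       arms = c("tislelizumab", "sorafenib"),
                       pat = patient(), wtp = 37653) {
  stopifnot(length(arms) == 2, inherits(spec, "psm_spec"))
  models <- lapply(stats::setNames(arms, arms), function(a)
    list(os = model_from_table(table, a, "os"),
         pfs = model_from_table(table, a, "pfs")))
  structure(list(table = table, spec = spec, arms = arms, models = models,
                 pat = pat, wtp = wtp), class = "cea_config")
}

#' Packaged base-case configuration
#'
#' @param ... Passed to [psm_spec()] to override run settings.
#' @export
default_config <- function(...) {
  cea_config(default_parameter_table(), spec = psm_spec(...))
}

# trajectories depend only on the survival models and spec, not on the
# economic parameters; cache them once per config for OWSA/PSA reuse
cea_trajectories <- function(config) {
  lapply(config$models, function(m)
    membership(config$spec, m$os, m$pfs))
}

# one deterministic run: given a (possibly perturbed) parameter table,
# rebuild both arms' economics and accumulate over cached trajectories
cea_run <- function(config, table = config$table, trajectories = NULL,
                    spec = config$spec) {
  if (is.null(trajectories)) trajectories <- cea_trajectories(config)
  arms <- lapply(stats::setNames(config$arms, config$arms), function(a)
    accumulate(trajectories[[a]],
               build_arm_economics(table, a, config$pat), spec))
  list(arms = arms,
       icer = icer(arms[[config$arms[1]]], arms[[config$arms[2]]]))
}

#' Run the base-case analysis
#'
#' @param config A [cea_config()]; defaults to the packaged base case.
#' @return List with per-arm `arm_result`s, the `icer_result`, and a
#'   one-row summary table in the published layout (cost and QALYs per
#'   arm, incremental cost and QALYs, ICER).
#' @export
base_case <- function(config = default_config()) {
  run <- cea_run(config)
  a1 <- run$arms[[config$arms[1]]]; a2 <- run$arms[[config$arms[2]]]
  run$summary <- data.frame(
    intervention = config$arms[1], comparator = config$arms[2],
    cost_intervention = a1$total_cost, qaly_intervention = a1$total_qaly,
    cost_comparator = a2$total_cost, qaly_comparator = a2$total_qaly,
    delta_cost = run$icer$delta_cost, delta_qaly = run$icer$delta_qaly,
    icer = run$icer$icer)
  run$config <- config
  class(run) <- "cea_result"
  run
}

#' @export
print.cea_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s: $%.2f, %.4f QALYs\n%s: $%.2f, %.4f QALYs\n",
              s$intervention, s$cost_intervention, s$qaly_intervention,
              s$comparator, s$cost_comparator, s$qaly_comparator))
  cat(sprintf("dC = $%.2f, dQALY = %.4f, ICER = $%.2f/QALY\n",
              s$delta_cost, s$delta_qaly, s$icer))
  invisible(x)
}
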