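#' Partitioned-survival-model run settings
#'
#' Three health states are modelled: progression-free (PFS), progressed
#' disease (PD) and death. State occupancy is read directly off the OS and
#' PFS curves each cycle.
#'
#' @param cycle_days Model cycle length in days (21, the dosing interval of
#'   the first-line regimens).
#' @param horizon_years Time horizon in years. The default 17 years is the
#'   residual life expectancy of the trial cohort and, given the heavy
#'   extrapolation tail of the fitted OS models, is the horizon under which
#'   the published base case is reproduced (see the methods vignette).
#' @param discount Annual discount rate applied to both costs and utilities
#'   (0.05 per Chinese pharmacoeconomic guidance).
#' @param half_cycle If `TRUE`, accrue each cycle at its midpoint rather
#'   than its end (half-cycle correction).
#' @return A `psm_spec` object.
#' @export
psm_spec <- function(cycle_days = 21, horizon_years = 17, discount = 0.05,
                     half_cycle = FALSE) {
  stopifnot(cycle_days > 0, horizon_years > 0, discount >= 0, discount <= 1)
  structure(list(cycle_days = cycle_days, horizon_years = horizon_years,
                 discount = discount, half_cycle = half_cycle,
                 n_cycles = floor(horizon_years * 365.25 / cycle_days)),
            class = "psm_spec")
}

# 1 month = 30.4375 days (Julian year / 12)
DAYS_PER_MONTH <- 30.4375

#' Per-cycle discount factor
#'
#' `(1 + discount)^(-k * cycle_days / 365.25)` for cycle index `k`.
#'
#' @param cycle_index Cycle index (0-based); vectorized.
#' @param spec A [psm_spec()].
#' @export
discount_factor <- function(cycle_index, spec) {
  stopifnot(all(cycle_index >= 0))
  (1 + spec$discount)^(-cycle_index * spec$cycle_days / 365.25)
}

#' State membership trajectory
#'
#' At each accrual time `t_k`: `p_pfs = min(S_pfs, S_os)` (crossing curves
#' are repaired by clamping PFS to OS), `p_death = 1 - S_os`,
#' `p_pd = 1 - p_pfs - p_death`. Cycle 0 is the entry row `(1, 0, 0)`.
#' Accrual times are cycle ends, or cycle midpoints when
#' `spec$half_cycle` is set.
#'
#' @param spec A [psm_spec()].
#' @param os_model,pfs_model [psm_model()] objects for overall and
#'   progression-free survival (time in months).
#' @return Data frame: `cycle`, `time_months`, `p_pfs`, `p_pd`, `p_death`;
#'   rows sum to 1 exactly.
#' @export
membership <- function(spec, os_model, pfs_model) {
  stopifnot(inherits(spec, "psm_spec"))
  K <- spec$n_cycles
  k <- 0:K
  t_eval <- k * spec$cycle_days / DAYS_PER_MONTH
  if (spec$half_cycle) t_eval[-1] <- t_eval[-1] - spec$cycle_days / DAYS_PER_MONTH / 2
  s_os <- surv_prob(os_model, t_eval)
  s_pfs <- surv_prob(pfs_model, t_eval)
  p_pfs <- pmin(s_pfs, s_os)
  p_death <- 1 - s_os
  data.frame(cycle = k, time_months = t_eval,
             p_pfs = p_pfs, p_pd = 1 - p_pfs - p_death, p_death = p_death)
}

#' Accumulate discounted costs and QALYs for one arm
#'
#' QALYs: `sum_k df(k) * (p_pfs * u_pfs + p_pd * u_pd) * cycle_years`.
#' Costs: one-off expected adverse-event cost at entry plus
#' `sum_k df(k) * (p_pfs * c_pfs + p_pd * c_pd + (p_pfs + p_pd) * c_followup)`.
#' The entry row (cycle 0) carries no accrual; each cycle `k >= 1` is
#' weighted by the membership at its accrual time and discounted by `df(k)`.
#'
#' @param traj Trajectory from [membership()].
#' @param econ An [arm_economics()] object.
#' @param spec The [psm_spec()] used to build `traj`.
#' @return An `arm_result`: `total_cost`, `total_qaly`, and a per-cycle
#'   breakdown table.
#' @export
accumulate <- function(traj, econ, spec) {
  stopifnot(inherits(econ, "arm_economics"), inherits(spec, "psm_spec"))
  if (nrow(traj) != spec$n_cycles + 1) stop("trajectory/spec cycle mismatch")
  cycle_years <- spec$cycle_days / 365.25
  acc <- traj[traj$cycle >= 1, ]
  df <- discount_factor(acc$cycle, spec)
  u <- econ$utilities
  q_cycle <- df * (acc$p_pfs * u$u_pfs + acc$p_pd * u$u_pd) * cycle_years
  c_cycle <- df * (acc$p_pfs * econ$c_pfs_cycle + acc$p_pd * econ$c_pd_cycle +
                   (acc$p_pfs + acc$p_pd) * econ$c_followup)
  structure(list(
    total_cost = econ$one_off_ae_cost + sum(c_cycle),
    total_qaly = sum(q_cycle),
    currency = econ$currency,
    breakdown = data.frame(cycle = acc$cycle, time_months = acc$time_months,
                           discount = df, qaly = q_cycle, cost = c_cycle)),
    class = "arm_result")
}

#' @export
print.arm_result <- function(x, ...) {
  cat(sprintf("<arm_result> cost = $%.2f, QALYs = %.4f\n",
              x$total_cost, x$total_qaly))
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' @param intervention,comparator `arm_result` objects from [accumulate()].
#' @return An `icer_result`: `delta_cost`, `delta_qaly`, `icer` and a
#'   dominance `flag` (`"dominant"` when cheaper and more effective,
#'   `"dominated"` when costlier and less effective, `"undefined"` when
#'   `delta_qaly` is 0, else `"icer"`).
#' @export
icer <- function(intervention, comparator) {
  cur <- c(intervention$currency, comparator$currency)
  if (length(unique(cur)) > 1) {
    stop("cannot compare arms with different currencies: ",
         paste(cur, collapse = " vs "))
  }
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_qaly - comparator$total_qaly
  flag <- if (dc < 0 && de > 0) "dominant"
          else if (dc > 0 && de < 0) "dominated"
          else if (de == 0) "undefined"
          else "icer"
  structure(list(delta_cost = dc, delta_qaly = de,
                 icer = if (de != 0) dc / de else NA_real_, flag = flag),
            class = "icer_result")
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("<icer_result> dC = $%.2f, dQALY = %.4f, ICER = %s (%s)\n",
              x$delta_cost, x$delta_qaly,
              if (is.na(x$icer)) "NA" else sprintf("$%.2f/QALY", x$icer), x$flag))
  invisible(x)
}

#' Incremental net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost`; positive values favour the intervention
#' at that willingness-to-pay threshold.
#'
#' @param result An `icer_result`.
#' @param wtp Willingness to pay in USD/QALY (non-negative); vectorized.
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * result$delta_qaly - result$delta_cost
}
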