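#' Sensitivity-analysis parameter specifications
#'
#' One row per varied parameter: identity key, base value and range, and
#' the sampling distribution for probabilistic analysis. Ranges come from
#' the table's `low`/`high` columns (the published 95% intervals); when a
#' row has no range, the conventions are applied: costs +/- 20%,
#' adverse-event incidences +/- 10% (relative). Survival-model parameters
#' carry no ranges and are never varied.
#'
#' @param tab Parameter table (see [read_parameter_table()]).
#' @return Data frame `key, category, name, arm, base, low, high,
#'   distribution`, sorted alphabetically by key (the fixed sampling order
#'   of [run_psa()]).
#' @export
default_ranges <- function(tab) {
  rows <- tab[tab$category != "survival" &
                tab$distribution %in% c("gamma", "beta"), ]
  base <- as.numeric(rows$value)
  low <- rows$low; high <- rows$high
  fill <- is.na(low) | is.na(high)
  rel <- ifelse(rows$category == "risk_ae", 0.10, 0.20)
  low[fill] <- base[fill] * (1 - rel[fill])
  high[fill] <- base[fill] * (1 + rel[fill])
  if (any(low > base | base > high)) stop("need low <= base <= high")
  key <- paste0(rows$category, ".", rows$name,
                ifelse(rows$arm == "", "", paste0(".", rows$arm)))
  out <- data.frame(key = key, category = rows$category, name = rows$name,
                    arm = rows$arm, base = base, low = low, high = high,
                    distribution = rows$distribution)
  out[order(out$key), ]
}

#' Moment-matched sampling distribution for one parameter
#'
#' The published range is treated as a 95% interval, so
#' `SE = (high - low)/3.92`. Gamma: `shape = base^2/SE^2`,
#' `scale = SE^2/base`. Beta: `alpha = base * (base*(1-base)/SE^2 - 1)`,
#' `beta = alpha * (1-base)/base`. Either way the distribution mean equals
#' the base-case value.
#'
#' @param base,low,high Base value and range.
#' @param distribution `"gamma"` or `"beta"`.
#' @return List with the distribution name and its parameters (`se = 0`
#'   collapses to a point mass at `base`).
#' @export
distribution_params <- function(base, low, high, distribution) {
  se <- (high - low) / 3.92
  if (se == 0 || distribution == "fixed") {
    return(list(distribution = "fixed", base = base, se = 0))
  }
  if (distribution == "gamma") {
    list(distribution = "gamma", shape = base^2 / se^2, scale = se^2 / base,
         se = se)
  } else if (distribution == "beta") {
    if (base <= 0 || base >= 1) stop("beta requires base in (0, 1)")
    if (se^2 >= base * (1 - base)) stop("range too wide for a beta on [0, 1]")
    a <- base * (base * (1 - base) / se^2 - 1)
    list(distribution = "beta", alpha = a, beta = a * (1 - base) / base,
         se = se)
  } else {
    stop("unknown distribution '", distribution, "'")
  }
}

# draw one value from a spec row, consuming the current RNG stream
.sample_param <- function(row) {
  dp <- distribution_params(row$base, row$low, row$high, row$distribution)
  switch(dp$distribution,
         fixed = row$base,
         gamma = stats::rgamma(1, shape = dp$shape, scale = dp$scale),
         beta = stats::rbeta(1, dp$alpha, dp$beta))
}

# overwrite table values for the given spec keys
.apply_params <- function(tab, specs, values) {
  for (i in seq_len(nrow(specs))) {
    hit <- tab$category == specs$category[i] & tab$name == specs$name[i] &
      tab$arm == specs$arm[i]
    tab$value[hit] <- as.character(values[i])
  }
  tab
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each parameter is set in turn to its low and high value with everything
#' else at base, the model is re-solved, and the ICER swing
#' `|icer_high - icer_low|` recorded. A parameter evaluation that breaks
#' model validity is recorded as failed rather than silently dropped.
#'
#' @param config A [cea_config()].
#' @param specs Parameter specifications, by default
#'   [default_ranges()] of the config's table.
#' @return Data frame `param, icer_low, icer_high, swing, failed`, sorted
#'   by descending swing.
#' @export
owsa <- function(config, specs = default_ranges(config$table)) {
  traj <- cea_trajectories(config)
  eval_at <- function(i, col) {
    tab <- .apply_params(config$table, specs[i, , drop = FALSE], specs[[col]][i])
    out <- try(cea_run(config, tab, traj)$icer$icer, silent = TRUE)
    if (inherits(out, "try-error")) NA_real_ else out
  }
  lo <- vapply(seq_len(nrow(specs)), eval_at, numeric(1), col = "low")
  hi <- vapply(seq_len(nrow(specs)), eval_at, numeric(1), col = "high")
  out <- data.frame(param = specs$key, icer_low = lo, icer_high = hi,
                    swing = abs(hi - lo), failed = is.na(lo) | is.na(hi))
  out[order(-out$swing), ]
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over the non-fixed parameters: each draw samples every
#' parameter independently from its moment-matched distribution (in fixed
#' alphabetical key order from a single seeded stream), rebuilds both
#' arms' economics, re-runs the model (survival parameters held at base)
#' and records the incremental cost and QALYs. Draws violating validity
#' constraints (e.g. a progressed-state utility above the
#' progression-free utility) are resampled, up to 100 attempts each, and
#' counted.
#'
#' @param config A [cea_config()].
#' @param specs Parameter specifications (see [default_ranges()]).
#' @param n_draws Number of Monte Carlo draws (1000 in the base analysis).
#' @param seed Integer seed; fixing it makes the result bit-reproducible.
#' @return A `psa_result`: `draws` (data frame `delta_cost, delta_qaly`),
#'   `n_draws`, `seed`, `n_resampled`.
#' @export
run_psa <- function(config, specs = default_ranges(config$table),
                    n_draws = 1000, seed = 2024) {
  stopifnot(n_draws >= 1)
  specs <- specs[order(specs$key), ]
  set.seed(seed)
  traj <- cea_trajectories(config)
  dc <- de <- numeric(n_draws)
  n_resampled <- 0L
  for (d in seq_len(n_draws)) {
    for (attempt in 1:100) {
      vals <- vapply(seq_len(nrow(specs)), function(i)
        .sample_param(specs[i, ]), numeric(1))
      u_pfs <- vals[specs$key == "utility.utility_pfs"]
      u_pd <- vals[specs$key == "utility.utility_pd"]
      ok <- length(u_pfs) == 0 || length(u_pd) == 0 || u_pd <= u_pfs
      if (ok) {
        tab <- .apply_params(config$table, specs, vals)
        run <- try(cea_run(config, tab, traj), silent = TRUE)
        ok <- !inherits(run, "try-error")
      }
      if (ok) break
      n_resampled <- n_resampled + 1L
      if (attempt == 100) stop("could not draw a valid parameter set")
    }
    dc[d] <- run$icer$delta_cost
    de[d] <- run$icer$delta_qaly
  }
  structure(list(draws = data.frame(delta_cost = dc, delta_qaly = de),
                 n_draws = n_draws, seed = seed, n_resampled = n_resampled),
            class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the fraction of PSA draws with
#' positive incremental net monetary benefit `wtp * dQALY - dCost`.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param wtp_grid Willingness-to-pay grid in USD/QALY.
#' @return Data frame `wtp, probability`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 60000, by = 250)) {
  stopifnot(inherits(psa, "psa_result"))
  prob <- vapply(wtp_grid, function(w)
    mean(w * psa$draws$delta_qaly - psa$draws$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' WTP at which the acceptability curve first reaches a probability
#'
#' Linear interpolation between the bracketing grid points.
#'
#' @param ceac_tab Output of [ceac()].
#' @param prob Target probability (default 0.5).
#' @return WTP in USD/QALY, or `NA` if never reached on the grid.
#' @export
ceac_crossing <- function(ceac_tab, prob = 0.5) {
  i <- which(ceac_tab$probability >= prob)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(ceac_tab$wtp[1])
  p0 <- ceac_tab$probability[i - 1]; p1 <- ceac_tab$probability[i]
  w0 <- ceac_tab$wtp[i - 1]; w1 <- ceac_tab$wtp[i]
  if (p1 == p0) return(w1)
  w0 + (prob - p0) / (p1 - p0) * (w1 - w0)
}

#' Discount-rate scenario analysis
#'
#' One full deterministic run per annual discount rate, everything else at
#' base. Guideline range is 0-8%.
#'
#' @param config A [cea_config()].
#' @param rates Annual discount rates to evaluate.
#' @return Data frame with per-arm discounted totals and the ICER per rate.
#' @export
scenario_discount <- function(config, rates = c(0.03, 0.05, 0.08)) {
  stopifnot(all(rates >= 0 & rates <= 0.08))
  traj <- cea_trajectories(config)
  do.call(rbind, lapply(rates, function(r) {
    sp <- psm_spec(config$spec$cycle_days, config$spec$horizon_years, r,
                   config$spec$half_cycle)
    run <- cea_run(config, trajectories = traj, spec = sp)
    a1 <- run$arms[[config$arms[1]]]; a2 <- run$arms[[config$arms[2]]]
    data.frame(rate = r,
               cost_intervention = a1$total_cost, qaly_intervention = a1$total_qaly,
               cost_comparator = a2$total_cost, qaly_comparator = a2$total_qaly,
               delta_cost = run$icer$delta_cost, delta_qaly = run$icer$delta_qaly,
               icer = run$icer$icer)
  }))
}
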