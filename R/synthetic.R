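#' Synthetic two-arm trial specification
#'
#' Emulates the statistical structure the analysis assumes: per-arm true
#' OS and PFS models, administrative right censoring at a follow-up
#' cutoff, and independent exponential dropout. Defaults mirror the trial
#' the analysis draws on: 338 vs 324 patients and the base-case fitted
#' survival models, with a 33-month administrative cutoff.
#'
#' @param n_per_arm Named integer vector of per-arm sample sizes.
#' @param os_models,pfs_models Named lists of [psm_model()]s per arm;
#'   defaults are the packaged base-case models.
#' @param cutoff_months Administrative censoring time.
#' @param dropout_rate Exponential dropout rate per month.
#' @param seed RNG seed used by [simulate_trial()].
#' @export
trial_spec <- function(n_per_arm = c(tislelizumab = 338, sorafenib = 324),
                       os_models = NULL, pfs_models = NULL,
                       cutoff_months = 33, dropout_rate = 0.002,
                       seed = 301) {
  stopifnot(all(n_per_arm > 0), cutoff_months > 0, dropout_rate >= 0)
  if (is.null(os_models) || is.null(pfs_models)) {
    tab <- default_parameter_table()
    arms <- names(n_per_arm)
    if (is.null(os_models)) {
      os_models <- lapply(stats::setNames(arms, arms), function(a)
        model_from_table(tab, a, "os"))
    }
    if (is.null(pfs_models)) {
      pfs_models <- lapply(stats::setNames(arms, arms), function(a)
        model_from_table(tab, a, "pfs"))
    }
  }
  structure(list(n_per_arm = n_per_arm, os_models = os_models,
                 pfs_models = pfs_models, cutoff_months = cutoff_months,
                 dropout_rate = dropout_rate, seed = seed),
            class = "trial_spec")
}

#' Simulate a two-arm trial
#'
#' Event times are drawn by inverse-CDF from the true models. PFS times
#' are coupled to OS per patient by redrawing until `PFS <= OS`
#' (progression cannot follow death), which keeps the simulated KM curves
#' non-crossing. Censoring is the minimum of the administrative cutoff and
#' an exponential dropout time, shared between the two endpoints of a
#' patient.
#'
#' @param spec A [trial_spec()].
#' @return Data frame `time, event, arm, endpoint` (endpoint `"os"` /
#'   `"pfs"`), reproducible for a fixed `spec$seed`.
#' @export
simulate_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_spec"))
  set.seed(spec$seed)
  out <- list()
  for (arm in names(spec$n_per_arm)) {
    n <- spec$n_per_arm[[arm]]
    t_os <- surv_quantile(spec$os_models[[arm]], stats::runif(n))
    t_pfs <- surv_quantile(spec$pfs_models[[arm]], stats::runif(n))
    for (i in 1:1000) {
      bad <- which(t_pfs > t_os)
      if (length(bad) == 0) break
      t_pfs[bad] <- surv_quantile(spec$pfs_models[[arm]],
                                  stats::runif(length(bad)))
    }
    t_pfs <- pmin(t_pfs, t_os)  # residual violations after max redraws
    cens <- spec$cutoff_months
    if (spec$dropout_rate > 0) {
      cens <- pmin(cens, stats::rexp(n, spec$dropout_rate))
    }
    for (ep in c("os", "pfs")) {
      tt <- if (ep == "os") t_os else t_pfs
      out[[paste(arm, ep)]] <- data.frame(
        time = pmax(pmin(tt, cens), 1e-6),
        event = as.integer(tt <= cens), arm = arm, endpoint = ep)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Extract one arm/endpoint pseudo-IPD from a simulated trial
#'
#' @param trial Output of [simulate_trial()].
#' @param arm,endpoint Labels to select.
#' @export
trial_ipd <- function(trial, arm, endpoint) {
  ipd <- trial[trial$arm == arm & trial$endpoint == endpoint,
               c("time", "event")]
  rownames(ipd) <- NULL
  structure(ipd, arm = arm, endpoint = endpoint,
            class = c("pseudo_ipd", "data.frame"))
}

#' Digitize pseudo-IPD into KM coordinates and a risk table
#'
#' Emulates the output of manual curve digitization: the product-limit
#' estimate sampled at a grid of times (step-function values, optionally
#' with small uniform jitter on the survival axis emulating digitization
#' noise) plus numbers-at-risk counts at the requested times.
#'
#' @param ipd Data frame with `time` and `event`.
#' @param grid Time grid for the digitized coordinates (months).
#' @param risk_times Times of the numbers-at-risk table (must start at 0).
#' @param jitter Half-width of the uniform survival jitter (default 0.005;
#'   use 0 for noise-free coordinates). Jittered coordinates are cleaned
#'   by [km_curve()] (clamping + isotonic clipping).
#' @return List with `curve` ([km_curve()]) and `risk` ([risk_table()]).
#' @export
digitize <- function(ipd, grid, risk_times = NULL, jitter = 0.005) {
  ipd <- as_ipd(ipd)
  km <- km_estimate(ipd)
  s <- km_survival_at(km, grid)
  if (jitter > 0) {
    s <- s + stats::runif(length(s), -jitter, jitter)
  }
  if (is.null(risk_times)) risk_times <- grid[grid <= max(ipd$time)]
  if (risk_times[1] != 0) risk_times <- c(0, risk_times)
  n_risk <- vapply(risk_times, function(r) sum(ipd$time >= r), numeric(1))
  keep <- n_risk > 0
  list(curve = km_curve(grid, s, arm = attr(ipd, "arm"),
                        endpoint = attr(ipd, "endpoint")),
       risk = risk_table(risk_times[keep], n_risk[keep]))
}
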