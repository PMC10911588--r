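#' Digitized Kaplan-Meier curve
#'
#' Container for digitized survival coordinates, with the cleaning applied
#' to real digitizer output: coordinates sorted by time, survival clamped to
#' `[0, 1]` and forced monotone non-increasing (isotonic clipping via a
#' running minimum), and the anchor point `(0, 1)` prepended when absent.
#'
#' @param time Times in months (non-negative).
#' @param surv Survival probabilities.
#' @param arm,endpoint Optional labels (e.g. `"tislelizumab"`, `"OS"`).
#' @param clean Apply the cleaning steps (default `TRUE`); with
#'   `clean = FALSE` invalid coordinates raise an error instead.
#' @return A `km_curve` object (data frame `time`, `surv` + labels).
#' @export
km_curve <- function(time, surv, arm = NA_character_, endpoint = NA_character_,
                     clean = TRUE) {
  if (length(time) != length(surv) || length(time) == 0) {
    stop("time and surv must be non-empty and of equal length")
  }
  if (any(time < 0)) stop("negative times in digitized curve")
  o <- order(time)
  time <- time[o]; surv <- surv[o]
  if (anyDuplicated(time)) stop("duplicated times in digitized curve")
  if (clean) {
    surv <- pmin(pmax(surv, 0), 1)
    surv <- cummin(surv)
    if (time[1] > 0) { time <- c(0, time); surv <- c(1, surv) }
    else surv[1] <- 1
  } else {
    if (any(diff(surv) > 0)) stop("survival must be non-increasing")
    if (any(surv < 0 | surv > 1)) stop("survival outside [0, 1]")
    if (time[1] != 0 || surv[1] != 1) stop("curve must start at (0, 1)")
  }
  structure(data.frame(time = time, surv = surv),
            arm = arm, endpoint = endpoint,
            class = c("km_curve", "data.frame"))
}

#' Numbers-at-risk table
#'
#' @param time Interval start times in months, strictly increasing from 0.
#' @param n_risk Number at risk at each time, non-increasing, non-negative.
#' @return A `risk_table` object.
#' @export
risk_table <- function(time, n_risk) {
  if (length(time) != length(n_risk) || length(time) == 0) {
    stop("time and n_risk must be non-empty and of equal length")
  }
  if (time[1] != 0) stop("risk table must start at time 0")
  if (any(diff(time) <= 0)) stop("risk-table times must be strictly increasing")
  if (any(n_risk < 0) || any(diff(n_risk) > 0)) {
    stop("n_risk must be non-negative and non-increasing")
  }
  if (n_risk[1] <= 0) stop("initial number at risk must be > 0")
  structure(data.frame(time = time, n_risk = round(n_risk)),
            class = c("risk_table", "data.frame"))
}

# survival step-function lookup S(t) of a km_curve
km_survival_at <- function(curve, times) {
  stats::approx(curve$time, curve$surv, xout = times, method = "constant",
                rule = 2, f = 0)$y
}

#' Reconstruct pseudo individual patient data from a published KM curve
#'
#' Inverts digitized Kaplan-Meier coordinates plus a numbers-at-risk table
#' into per-patient `(time, event)` records, following the standard
#' published-curve reconstruction algorithm: within each risk-table
#' interval censoring times are assumed uniformly distributed, the censoring
#' count is solved iteratively so the implied number at risk matches the
#' published table at the next interval boundary, and event counts at each
#' digitized drop are chosen so the re-estimated product-limit curve tracks
#' the digitized coordinates. Placement is deterministic (no RNG).
#'
#' @param curve A [km_curve()].
#' @param risk A [risk_table()]; if `NULL`, a lower-fidelity fallback assumes
#'   no censoring before the last digitized time and warns.
#' @param total_events Optional total event count used to reconcile the
#'   censoring level of the final interval.
#' @param n0 Initial number at risk; only needed for the risk-table-free
#'   fallback.
#' @return Data frame `time`, `event` with `nrow` equal to the initial
#'   number at risk; attributes `arm`/`endpoint` copied from the curve.
#' @export
reconstruct_ipd <- function(curve, risk = NULL, total_events = NULL,
                            n0 = NULL) {
  stopifnot(inherits(curve, "km_curve"))
  if (is.null(risk)) {
    warning("no numbers-at-risk table supplied; assuming no censoring before ",
            "the last digitized time (lower-fidelity reconstruction)")
    if (is.null(n0)) stop("risk-table-free reconstruction needs n0")
    risk <- risk_table(0, n0)
  }
  stopifnot(inherits(risk, "risk_table"))
  tt <- curve$time; ss <- curve$surv
  if (risk$time[1] > tt[1]) stop("curve and risk table do not cover the same range")
  J <- length(tt); I <- nrow(risk)
  t_end <- max(tt[J], risk$time[I])
  # interval i is (risk_time_i, risk_time_{i+1}]: a drop digitized exactly at
  # a boundary belongs to the earlier interval, so the published number at
  # risk at that boundary is the post-drop count
  bounds <- c(risk$time, t_end + 1e-9)

  ev_time <- numeric(0); ev_n <- integer(0); cen_times <- numeric(0)
  ncur <- risk$n_risk[1]; km_prev <- 1

  for (i in seq_len(I)) {
    lo_t <- bounds[i]; hi_t <- bounds[i + 1]
    idx <- which(tt > lo_t & tt <= hi_t & ss < 1)
    target <- if (i < I) risk$n_risk[i + 1] else NA_integer_
    # state at interval entry, restored on each censoring guess
    st <- list(ncur = ncur, km = km_prev)
    guess <- 0L
    best <- NULL
    for (iter in 1:200) {
      ncur <- st$ncur; km_prev <- st$km
      cen <- if (guess > 0) lo_t + seq_len(guess) / (guess + 1) * (hi_t - lo_t) else numeric(0)
      d_here <- integer(length(idx)); t_here <- tt[idx]
      prev_t <- lo_t
      n_removed <- 0L
      for (k in seq_along(idx)) {
        j <- idx[k]
        # censorings strictly before the drop leave the risk set first;
        # a censor time tied with a drop stays at risk through it
        w <- sum(cen > prev_t & cen < tt[j])
        ncur <- ncur - w
        n_removed <- n_removed + w
        d <- if (km_prev > 0) round(ncur * (1 - ss[j] / km_prev)) else 0
        d <- max(0L, min(d, ncur))
        if (d > 0) { km_prev <- km_prev * (1 - d / ncur); ncur <- ncur - d }
        d_here[k] <- d
        prev_t <- tt[j]
      }
      ncur <- ncur - (length(cen) - n_removed)
      if (is.na(target)) {
        # final interval: reconcile against total event count if given
        if (is.null(total_events)) { best <- list(cen = cen, d = d_here, ncur = ncur, km = km_prev); break }
        D <- sum(ev_n) + sum(d_here)
        miss <- D - total_events
        if (is.null(best) || abs(miss) < best$miss) {
          best <- list(cen = cen, d = d_here, ncur = ncur, km = km_prev, miss = abs(miss))
        }
        if (miss == 0) break
        newg <- max(0L, min(st$ncur, guess + miss))
        if (newg == guess) break
        guess <- newg
      } else {
        miss <- ncur - target
        if (is.null(best) || abs(miss) < best$miss) {
          best <- list(cen = cen, d = d_here, ncur = ncur, km = km_prev, miss = abs(miss))
        }
        if (miss == 0) break
        newg <- max(0L, min(st$ncur, guess + miss))
        if (newg == guess) break
        guess <- newg
      }
    }
    ev_time <- c(ev_time, tt[idx]); ev_n <- c(ev_n, best$d)
    cen_times <- c(cen_times, best$cen)
    ncur <- best$ncur; km_prev <- best$km
  }

  out_t <- c(rep(ev_time, ev_n), cen_times, rep(t_end, ncur))
  out_e <- c(rep(1L, sum(ev_n)), rep(0L, length(cen_times)), rep(0L, ncur))
  out_t <- pmax(out_t, 1e-6)  # times must be strictly positive
  o <- order(out_t, -out_e)
  structure(data.frame(time = out_t[o], event = out_e[o]),
            arm = attr(curve, "arm"), endpoint = attr(curve, "endpoint"),
            class = c("pseudo_ipd", "data.frame"))
}

#' Product-limit (Kaplan-Meier) estimate of pseudo-IPD
#'
#' Thin wrapper over [survival::survfit()] returning a [km_curve()] with
#' steps at event times only.
#'
#' @param ipd Data frame with `time` and `event`.
#' @return A `km_curve`.
#' @export
km_estimate <- function(ipd) {
  ipd <- as_ipd(ipd)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = data.frame(time = ipd$time, event = ipd$event),
                          conf.type = "none")
  keep <- sf$n.event > 0
  km_curve(c(0, sf$time[keep]), c(1, sf$surv[keep]),
           arm = attr(ipd, "arm"), endpoint = attr(ipd, "endpoint"),
           clean = FALSE)
}
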