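#' Right-censored log-likelihood
#'
#' Sum of `log f(t)` over events plus `log S(t)` over censored records.
#'
#' @param model A [psm_model()].
#' @param ipd Data frame with columns `time` (months, > 0) and `event`
#'   (1 = event, 0 = right-censored).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(model, ipd) {
  ipd <- as_ipd(ipd)
  if (any(ipd$time <= 0)) stop("all times must be > 0")
  ev <- ipd$event == 1
  ll <- 0
  if (any(ev)) ll <- ll + sum(surv_logdens(model, ipd$time[ev]))
  if (any(!ev)) ll <- ll + sum(log(surv_prob(model, ipd$time[!ev])))
  ll
}

# minimal coercion/validation of pseudo-IPD data frames
as_ipd <- function(ipd) {
  if (is.null(ipd$time) && !is.null(ipd$time_months)) ipd$time <- ipd$time_months
  if (is.null(ipd$time) || is.null(ipd$event)) {
    stop("ipd needs columns 'time' (or 'time_months') and 'event'")
  }
  if (nrow(ipd) == 0) stop("empty ipd")
  if (!all(ipd$event %in% c(0, 1))) stop("event must be 0/1")
  ipd
}

# unconstrained <-> natural parameter transforms (log for positive parameters)
.par_transform <- function(family) {
  pos <- .family_params[[family]] %in% .family_positive[[family]]
  list(
    to_opt   = function(p) { p[pos] <- log(p[pos]); p },
    from_opt = function(x) { x[pos] <- exp(x[pos]); x }
  )
}

# crude starting values from the event-time distribution
.start_values <- function(family, ipd) {
  ev_t <- ipd$time[ipd$event == 1]
  rate0 <- sum(ipd$event) / sum(ipd$time)            # exponential MLE
  ml <- mean(log(ev_t)); sl <- max(stats::sd(log(ev_t)), 0.1)
  switch(family,
    exponential = c(rate = rate0),
    weibull     = c(shape = 1, scale = 1 / rate0),
    lognormal   = c(meanlog = ml, sdlog = sl),
    loglogistic = c(shape = 1 / sl, scale = exp(ml)),
    gompertz    = c(shape = 1e-3, rate = rate0),
    gengamma    = c(mu = ml, sigma = sl, Q = 0.1)
  )
}

#' Fit a parametric survival model by maximum likelihood
#'
#' Multi-start quasi-Newton (BFGS) optimization of the right-censored
#' log-likelihood on transformed parameters (log scale for positive ones).
#' Starts at method-of-moments style values plus two deterministically
#' perturbed restarts; the best converged solution is kept.
#'
#' @param family One of [families()].
#' @param ipd Data frame with `time` and `event` columns.
#' @return A `psm_fit` object: `model`, `loglik`, `aic`, `bic`, `n`,
#'   `converged`.
#' @export
fit_mle <- function(family, ipd) {
  family <- match.arg(family, families())
  ipd <- as_ipd(ipd)
  if (any(ipd$time <= 0)) stop("all times must be > 0")
  k <- length(.family_params[[family]])
  if (sum(ipd$event) < k) {
    stop("need at least ", k, " events to fit a ", family, " model")
  }
  tr <- .par_transform(family)
  negll <- function(x) {
    p <- tr$from_opt(x)
    m <- try(psm_model(family, p), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    ll <- try(suppressWarnings(log_likelihood(m, ipd)), silent = TRUE)
    if (inherits(ll, "try-error") || !is.finite(ll)) return(1e10)
    -ll
  }
  p0 <- .start_values(family, ipd)
  # deterministic restarts: same reproducibility as a fixed seed, no RNG used
  starts <- list(p0,
                 tr$from_opt(tr$to_opt(p0) + 0.3),
                 tr$from_opt(tr$to_opt(p0) - 0.3))
  best <- NULL
  for (s in starts) {
    o <- try(stats::optim(tr$to_opt(s), negll, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("optimization failed for family '", family, "'")
  model <- psm_model(family, tr$from_opt(best$par))
  ll <- -best$value
  n <- nrow(ipd)
  structure(list(model = model, loglik = ll,
                 aic = -2 * ll + 2 * k,
                 bic = -2 * ll + k * log(n),
                 n = n, converged = best$convergence == 0),
            class = "psm_fit")
}

#' @export
print.psm_fit <- function(x, ...) {
  cat(sprintf("<psm_fit> %s  loglik=%.3f  AIC=%.2f  BIC=%.2f  n=%d  converged=%s\n",
              x$model$family, x$loglik, x$aic, x$bic, x$n, x$converged))
  invisible(x)
}

#' Select the best fit by information criterion
#'
#' @param fits List of `psm_fit` objects on the same data.
#' @param criterion `"aic"` or `"bic"`.
#' @return The fit with minimal criterion; exact ties are broken by the
#'   family order of [families()].
#' @export
select_best <- function(fits, criterion = c("aic", "bic")) {
  criterion <- match.arg(criterion)
  if (length(fits) == 0) stop("empty fit list")
  crit <- vapply(fits, function(f) f[[criterion]], numeric(1))
  fam_rank <- match(vapply(fits, function(f) f$model$family, character(1)),
                    families())
  fits[[order(crit, fam_rank)[1]]]
}

#' Tabulate a list of fits
#'
#' @param fits List of `psm_fit` objects.
#' @return Data frame: family, parameter string, loglik, aic, bic, converged.
#' @export
fit_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(family = f$model$family,
               params = paste(sprintf("%s=%.6g", names(f$model$params),
                                      f$model$params), collapse = ";"),
               loglik = f$loglik, aic = f$aic, bic = f$bic,
               n = f$n, converged = f$converged)
  }))
}
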