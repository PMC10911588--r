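#' Parametric survival families
#'
#' The six families used for extrapolating the trial's overall- and
#' progression-free-survival curves: exponential, Weibull, log-normal,
#' log-logistic, Gompertz and the three-parameter generalized gamma in the
#' Prentice `(mu, sigma, Q)` parameterization, which nests the Weibull
#' (`Q = 1`) and the log-normal (`Q = 0`).
#'
#' @return Character vector of family names, in the canonical order used
#'   for deterministic tie-breaking in [select_best()].
#' @export
families <- function() {
  c("exponential", "weibull", "lognormal", "loglogistic", "gompertz", "gengamma")
}

# parameter names per family; order matters (it is the `params` vector order)
.family_params <- list(
  exponential = "rate",
  weibull     = c("shape", "scale"),
  lognormal   = c("meanlog", "sdlog"),
  loglogistic = c("shape", "scale"),
  gompertz    = c("shape", "rate"),
  gengamma    = c("mu", "sigma", "Q")
)

# which parameters must be strictly positive
.family_positive <- list(
  exponential = "rate",
  weibull     = c("shape", "scale"),
  lognormal   = "sdlog",
  loglogistic = c("shape", "scale"),
  gompertz    = "rate",
  gengamma    = "sigma"
)

#' Construct a parametric survival model
#'
#' @param family One of [families()].
#' @param params Named (or positional) numeric vector of parameters:
#'   `exponential(rate)`, `weibull(shape, scale)`, `lognormal(meanlog, sdlog)`,
#'   `loglogistic(shape, scale)`, `gompertz(shape, rate)`,
#'   `gengamma(mu, sigma, Q)`. Scale-type parameters are on the month scale.
#' @param time_unit Unit of the time axis; only `"months"` is used here.
#' @return An object of class `psm_model`.
#' @examples
#' m <- psm_model("lognormal", c(meanlog = 2.783, sdlog = 1.18198))
#' surv_prob(m, c(0, 12, 24))
#' @export
psm_model <- function(family, params, time_unit = "months") {
  family <- match.arg(family, families())
  pn <- .family_params[[family]]
  params <- as.numeric(params)
  if (length(params) != length(pn)) {
    stop("family '", family, "' needs ", length(pn), " parameters (",
         paste(pn, collapse = ", "), "), got ", length(params))
  }
  names(params) <- pn
  if (any(!is.finite(params))) stop("non-finite parameters")
  pos <- .family_positive[[family]]
  if (any(params[pos] <= 0)) {
    stop("parameters must be > 0: ", paste(pos[params[pos] <= 0], collapse = ", "))
  }
  structure(list(family = family, params = params, time_unit = time_unit),
            class = "psm_model")
}

#' @export
print.psm_model <- function(x, ...) {
  cat("<psm_model>", x$family, "(",
      paste(sprintf("%s = %g", names(x$params), x$params), collapse = ", "),
      "), time in", x$time_unit, "\n")
  invisible(x)
}

# ---- generalized gamma (Prentice) ------------------------------------------
# w = (log t - mu)/sigma, a = Q^-2, u = a * exp(Q * w)
# S(t) = 1 - P(a, u) for Q > 0,  P(a, u) for Q < 0, log-normal limit at Q = 0,
# with P the regularized lower incomplete gamma function.

.gg_eps <- 1e-8

gengamma_surv <- function(t, mu, sigma, Q) {
  if (abs(Q) < .gg_eps) {
    return(stats::plnorm(t, mu, sigma, lower.tail = FALSE))
  }
  a <- Q^-2
  w <- (suppressWarnings(log(t)) - mu) / sigma
  u <- a * exp(Q * w)
  s <- if (Q > 0) stats::pgamma(u, a, lower.tail = FALSE) else stats::pgamma(u, a)
  s[t <= 0] <- 1
  s
}

gengamma_logdens <- function(t, mu, sigma, Q) {
  if (abs(Q) < .gg_eps) {
    return(stats::dlnorm(t, mu, sigma, log = TRUE))
  }
  a <- Q^-2
  w <- (log(t) - mu) / sigma
  log(abs(Q)) - log(sigma * t) - lgamma(a) + a * log(a) + a * (Q * w - exp(Q * w))
}

gengamma_squantile <- function(p, mu, sigma, Q) {
  # t such that S(t) = p; closed form through the gamma quantile function
  if (abs(Q) < .gg_eps) {
    return(stats::qlnorm(p, mu, sigma, lower.tail = FALSE))
  }
  a <- Q^-2
  u <- if (Q > 0) stats::qgamma(p, a, lower.tail = FALSE) else stats::qgamma(p, a)
  w <- log(u / a) / Q
  exp(mu + sigma * w)
}

# ---- Gompertz (shape a real, rate b > 0): H(t) = b/a (exp(a t) - 1) --------

gompertz_surv <- function(t, shape, rate) {
  h <- if (abs(shape) < 1e-12) rate * t else rate / shape * expm1(shape * t)
  s <- exp(-h)
  s[t <= 0] <- 1
  s
}

gompertz_logdens <- function(t, shape, rate) {
  h <- if (abs(shape) < 1e-12) rate * t else rate / shape * expm1(shape * t)
  log(rate) + shape * t - h
}

gompertz_squantile <- function(p, shape, rate) {
  if (abs(shape) < 1e-12) return(-log(p) / rate)
  x <- 1 - shape / rate * log(p)
  # negative shape: hazard decays, survival plateaus at exp(rate/shape)
  out <- ifelse(x > 0, log(x) / shape, Inf)
  out
}

# ---- log-logistic (shape a > 0, scale s > 0): S = 1/(1 + (t/s)^a) ----------

llogis_surv <- function(t, shape, scale) {
  s <- 1 / (1 + (t / scale)^shape)
  s[t <= 0] <- 1
  s
}

llogis_logdens <- function(t, shape, scale) {
  z <- (t / scale)^shape
  log(shape) - log(t) + log(z) - 2 * log1p(z)
}

llogis_squantile <- function(p, shape, scale) {
  scale * ((1 - p) / p)^(1 / shape)
}

# ---- generic dispatch -------------------------------------------------------

#' Survival function of a parametric model
#'
#' @param model A [psm_model()].
#' @param t Time(s) in months, `t >= 0`.
#' @return `S(t)`, with `S(0) = 1`, non-increasing in `t`.
#' @export
surv_prob <- function(model, t) {
  stopifnot(inherits(model, "psm_model"))
  if (any(t < 0)) stop("negative time")
  p <- model$params
  unname(switch(model$family,
    exponential = stats::pexp(t, p["rate"], lower.tail = FALSE),
    weibull     = stats::pweibull(t, p["shape"], p["scale"], lower.tail = FALSE),
    lognormal   = stats::plnorm(t, p["meanlog"], p["sdlog"], lower.tail = FALSE),
    loglogistic = llogis_surv(t, p["shape"], p["scale"]),
    gompertz    = gompertz_surv(t, p["shape"], p["rate"]),
    gengamma    = gengamma_surv(t, p["mu"], p["sigma"], p["Q"])
  ))
}

#' Log density of a parametric model
#'
#' @inheritParams surv_prob
#' @return `log f(t)`; `t` must be strictly positive.
#' @export
surv_logdens <- function(model, t) {
  stopifnot(inherits(model, "psm_model"))
  if (any(t <= 0)) stop("log density requires t > 0")
  p <- model$params
  unname(switch(model$family,
    exponential = stats::dexp(t, p["rate"], log = TRUE),
    weibull     = stats::dweibull(t, p["shape"], p["scale"], log = TRUE),
    lognormal   = stats::dlnorm(t, p["meanlog"], p["sdlog"], log = TRUE),
    loglogistic = llogis_logdens(t, p["shape"], p["scale"]),
    gompertz    = gompertz_logdens(t, p["shape"], p["rate"]),
    gengamma    = gengamma_logdens(t, p["mu"], p["sigma"], p["Q"])
  ))
}

#' Survival quantile (inverse survival function)
#'
#' Returns the time `t` at which `S(t) = p`. Closed forms exist for every
#' family; a Gompertz model with negative shape plateaus and returns `Inf`
#' for `p` below the plateau.
#'
#' @param model A [psm_model()].
#' @param p Survival probabilities in `(0, 1]`.
#' @export
surv_quantile <- function(model, p) {
  stopifnot(inherits(model, "psm_model"))
  if (any(p <= 0 | p > 1)) stop("p must be in (0, 1]")
  pa <- model$params
  unname(switch(model$family,
    exponential = stats::qexp(p, pa["rate"], lower.tail = FALSE),
    weibull     = stats::qweibull(p, pa["shape"], pa["scale"], lower.tail = FALSE),
    lognormal   = stats::qlnorm(p, pa["meanlog"], pa["sdlog"], lower.tail = FALSE),
    loglogistic = llogis_squantile(p, pa["shape"], pa["scale"]),
    gompertz    = gompertz_squantile(p, pa["shape"], pa["rate"]),
    gengamma    = gengamma_squantile(p, pa["mu"], pa["sigma"], pa["Q"])
  ))
}

#' Median survival time
#'
#' @param model A [psm_model()].
#' @return Time in months with `S(t) = 0.5` (`Inf` for a plateauing
#'   Gompertz whose plateau exceeds 0.5).
#' @export
median_survival <- function(model) {
  unname(surv_quantile(model, 0.5))
}
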