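# shared fixtures, all built in code

# base-case survival models (the fitted parameters of the two trial arms)
base_models <- function() {
  tab <- default_parameter_table()
  list(
    os_tis  = model_from_table(tab, "tislelizumab", "os"),
    pfs_tis = model_from_table(tab, "tislelizumab", "pfs"),
    os_sor  = model_from_table(tab, "sorafenib", "os"),
    pfs_sor = model_from_table(tab, "sorafenib", "pfs")
  )
}

# one representative valid model per family
example_models <- function() {
  list(
    psm_model("exponential", c(rate = 0.08)),
    psm_model("weibull", c(shape = 1.3, scale = 14)),
    psm_model("lognormal", c(meanlog = 2.5, sdlog = 0.9)),
    psm_model("loglogistic", c(shape = 1.8, scale = 11)),
    psm_model("gompertz", c(shape = 0.05, rate = 0.04)),
    psm_model("gengamma", c(mu = 2.57, sigma = 1.40, Q = -0.65))
  )
}

# simulate right-censored data from a model (uniform censoring)
simulate_censored <- function(model, n, cens_max = Inf, seed = 1) {
  set.seed(seed)
  tt <- surv_quantile(model, stats::runif(n))
  cen <- if (is.finite(cens_max)) stats::runif(n, 0, cens_max) else rep(Inf, n)
  data.frame(time = pmax(pmin(tt, cen), 1e-9), event = as.integer(tt <= cen))
}

# an arm_economics object with simple round numbers for hand arithmetic
toy_economics <- function(c_pfs = 100, c_pd = 200, c_fu = 10, ae = 50,
                          u_pfs = 0.76, u_pd = 0.68) {
  arm_economics(c_pfs, c_pd, c_fu, ae, utility_set(u_pfs, u_pd))
}
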