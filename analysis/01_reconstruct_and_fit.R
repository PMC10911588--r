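#!/usr/bin/env Rscript
# Survival-curve reconstruction and parametric fitting, demonstrated on a
# synthetic two-arm trial with the structure of the source data (338 vs 324
# patients, the base-case fitted models as truth, 33-month follow-up).
#
# The published analysis digitized the trial's KM figures and reconstructed
# pseudo individual patient data before fitting six parametric families and
# choosing by AIC/BIC. The trial's raw curves are not redistributable, so
# this driver runs the identical pipeline on simulated curves; the packaged
# base case uses the published fitted parameters directly.
#
# Writes: results/fit_<arm>_<endpoint>.csv, results/reconstruction_check.csv

library(psmcea)
dir.create("results", showWarnings = FALSE)

ts <- trial_spec(seed = 301)
trial <- simulate_trial(ts)

check <- NULL
for (arm in names(ts$n_per_arm)) {
  for (ep in c("os", "pfs")) {
    ipd <- trial_ipd(trial, arm, ep)
    dg <- digitize(ipd, grid = seq(0, 33, by = 0.25),
                   risk_times = seq(0, 33, by = 3), jitter = 0)
    rec <- reconstruct_ipd(dg$curve, dg$risk)

    # round-trip fidelity of the reconstruction
    err <- abs(psmcea:::km_survival_at(km_estimate(rec), dg$curve$time) -
                 dg$curve$surv)
    check <- rbind(check, data.frame(arm = arm, endpoint = ep,
                                     n = nrow(rec), max_km_error = max(err)))

    # all six families on the reconstructed records, ranked by AIC
    fits <- suppressWarnings(lapply(families(), fit_mle, ipd = rec))
    tab <- fit_table(fits)
    tab <- tab[order(tab$aic), ]
    write.csv(tab, sprintf("results/fit_%s_%s.csv", arm, ep),
              row.names = FALSE)
    cat(sprintf("%s %s: best by AIC = %s, by BIC = %s\n", arm, ep,
                select_best(fits, "aic")$model$family,
                select_best(fits, "bic")$model$family))
  }
}
write.csv(check, "results/reconstruction_check.csv", row.names = FALSE)
cat("\nKM round-trip error by arm/endpoint (all should be < 0.02):\n")
print(check, row.names = FALSE)
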