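test_that("membership starts at (1, 0, 0) and sums to 1 every cycle", {
  bm <- base_models()
  spec <- psm_spec()
  for (arm in list(c("os_tis", "pfs_tis"), c("os_sor", "pfs_sor"))) {
    traj <- membership(spec, bm[[arm[1]]], bm[[arm[2]]])
    expect_equal(nrow(traj), spec$n_cycles + 1)
    expect_equal(unlist(traj[1, c("p_pfs", "p_pd", "p_death")]),
                 c(p_pfs = 1, p_pd = 0, p_death = 0))
    expect_equal(traj$p_pfs + traj$p_pd + traj$p_death,
                 rep(1, nrow(traj)), tolerance = 1e-14)
    expect_true(all(traj$p_pfs >= 0 & traj$p_pd >= 0 & traj$p_death >= 0))
    # PFS occupancy never exceeds overall survival
    expect_true(all(traj$p_pfs <= 1 - traj$p_death + 1e-14))
  }
})

test_that("membership is partitioned survival arithmetic, with clamping", {
  spec <- psm_spec(horizon_years = 1)
  # S_os(t) = 0.8, S_pfs(t) = 0.5 at some t: occupancy (0.5, 0.3, 0.2)
  t1 <- 21 / 30.4375
  os <- psm_model("exponential", -log(0.8) / t1)
  pfs <- psm_model("exponential", -log(0.5) / t1)
  traj <- membership(spec, os, pfs)
  expect_equal(unlist(traj[2, c("p_pfs", "p_pd", "p_death")]),
               c(p_pfs = 0.5, p_pd = 0.3, p_death = 0.2), tolerance = 1e-10)
  # crossing curves: S_os = 0.4 < S_pfs = 0.5 clamps PD occupancy to zero
  os2 <- psm_model("exponential", -log(0.4) / t1)
  traj2 <- membership(spec, os2, pfs)
  expect_equal(unlist(traj2[2, c("p_pfs", "p_pd", "p_death")]),
               c(p_pfs = 0.4, p_pd = 0, p_death = 0.6), tolerance = 1e-10)
})

test_that("discount factors follow the annual rate on the day scale", {
  spec <- psm_spec(discount = 0.05)
  expect_equal(discount_factor(0, spec), 1)
  # one year is 365.25/21 cycles
  expect_equal(discount_factor(365.25 / 21, spec), 1 / 1.05, tolerance = 1e-12)
  spec0 <- psm_spec(discount = 0)
  expect_equal(discount_factor(0:50, spec0), rep(1, 51))
})

test_that("accumulation reproduces hand arithmetic on degenerate cases", {
  # alive forever in PFS, utility 1, no discounting, one-year horizon
  spec <- psm_spec(horizon_years = 1, discount = 0)
  os <- psm_model("exponential", 1e-12)
  traj <- membership(spec, os, os)
  econ <- arm_economics(0, 0, 0, 0, utility_set(1, 1))
  res <- accumulate(traj, econ, spec)
  # 17 whole cycles cover 357 of 365.25 days: QALY = 1 minus the remainder
  expect_equal(res$total_qaly, 17 * 21 / 365.25, tolerance = 1e-10)
  expect_equal(res$total_qaly, 1, tolerance = 0.03)
  expect_equal(res$total_cost, 0)

  # single-cycle toy with known membership and costs
  spec1 <- psm_spec(horizon_years = 22 / 365.25, discount = 0.05)
  t1 <- 21 / 30.4375
  os1 <- psm_model("exponential", -log(0.8) / t1)
  pfs1 <- psm_model("exponential", -log(0.5) / t1)
  traj1 <- membership(spec1, os1, pfs1)
  expect_equal(nrow(traj1), 2)
  econ1 <- toy_economics(c_pfs = 100, c_pd = 200, c_fu = 10, ae = 50)
  res1 <- accumulate(traj1, econ1, spec1)
  df1 <- 1.05^(-21 / 365.25)
  expect_equal(res1$total_qaly,
               df1 * (0.5 * 0.76 + 0.3 * 0.68) * 21 / 365.25, tolerance = 1e-12)
  expect_equal(res1$total_cost,
               50 + df1 * (0.5 * 100 + 0.3 * 200 + 0.8 * 10), tolerance = 1e-12)
})

test_that("discounted totals agree with continuous-time quadrature within 1%", {
  bm <- base_models()
  spec <- psm_spec()
  tab <- default_parameter_table()
  traj <- membership(spec, bm$os_tis, bm$pfs_tis)
  econ <- build_arm_economics(tab, "tislelizumab")
  res <- accumulate(traj, econ, spec)
  H <- spec$n_cycles * 21 / 30.4375   # months covered by whole cycles
  mo_per_yr <- 12
  disc <- function(t) 1.05^(-t / mo_per_yr)
  qaly_fun <- function(t) {
    s_os <- surv_prob(bm$os_tis, t); s_pfs <- pmin(surv_prob(bm$pfs_tis, t), s_os)
    disc(t) * (s_pfs * 0.76 + (s_os - s_pfs) * 0.68) / mo_per_yr
  }
  cost_fun <- function(t) {
    s_os <- surv_prob(bm$os_tis, t); s_pfs <- pmin(surv_prob(bm$pfs_tis, t), s_os)
    disc(t) * (s_pfs * econ$c_pfs_cycle + (s_os - s_pfs) * econ$c_pd_cycle +
                 s_os * econ$c_followup) / (21 / 30.4375)
  }
  q_ref <- stats::integrate(qaly_fun, 0, H, rel.tol = 1e-9, subdivisions = 2000)$value
  c_ref <- stats::integrate(cost_fun, 0, H, rel.tol = 1e-9, subdivisions = 2000)$value +
    econ$one_off_ae_cost
  expect_equal(res$total_qaly, q_ref, tolerance = 0.01)
  expect_equal(res$total_cost, c_ref, tolerance = 0.01)
})

test_that("with utilities 1 and no costs QALYs equal discounted RMST", {
  bm <- base_models()
  spec <- psm_spec()
  traj <- membership(spec, bm$os_sor, bm$pfs_sor)
  econ <- arm_economics(0, 0, 0, 0, utility_set(1, 1))
  res <- accumulate(traj, econ, spec)
  H <- spec$n_cycles * 21 / 30.4375
  rmst <- stats::integrate(function(t)
    1.05^(-t / 12) * surv_prob(bm$os_sor, t) / 12, 0, H,
    rel.tol = 1e-9, subdivisions = 2000)$value
  # end-of-cycle evaluation underestimates a steep early drop by ~ half a
  # cycle's worth of hazard; the discrepancy is pure discretization error
  expect_equal(res$total_qaly, rmst, tolerance = 0.02)
})

test_that("totals are non-increasing in the discount rate", {
  bm <- base_models()
  tab <- default_parameter_table()
  econ <- build_arm_economics(tab, "tislelizumab")
  prev_q <- Inf; prev_c <- Inf
  for (r in c(0, 0.03, 0.05, 0.08)) {
    spec <- psm_spec(discount = r)
    res <- accumulate(membership(spec, bm$os_tis, bm$pfs_tis), econ, spec)
    expect_lt(res$total_qaly, prev_q)
    expect_lt(res$total_cost, prev_c)
    prev_q <- res$total_qaly; prev_c <- res$total_cost
  }
})

test_that("results are stable under refinement of the cycle length", {
  bm <- base_models()
  tab <- default_parameter_table()
  econ <- build_arm_economics(tab, "tislelizumab")
  q <- vapply(c(21, 10.5), function(cd) {
    spec <- psm_spec(cycle_days = cd)
    accumulate(membership(spec, bm$os_tis, bm$pfs_tis), econ, spec)$total_qaly
  }, numeric(1))
  # end-of-cycle accrual has a first-order discretization error, so halving
  # the cycle moves totals by about half that error (~0.5% here)
  expect_lt(abs(q[2] / q[1] - 1), 0.01)
  # midpoint accrual is second-order accurate: halving barely moves it
  # (residual change is mostly the floor() of the horizon into whole cycles)
  qh <- vapply(c(21, 10.5), function(cd) {
    spec <- psm_spec(cycle_days = cd, half_cycle = TRUE)
    accumulate(membership(spec, bm$os_tis, bm$pfs_tis), econ, spec)$total_qaly
  }, numeric(1))
  expect_lt(abs(qh[2] / qh[1] - 1), 0.002)
})

test_that("half-cycle correction accrues at midpoints and raises QALYs slightly", {
  bm <- base_models()
  tab <- default_parameter_table()
  econ <- build_arm_economics(tab, "tislelizumab")
  run <- function(half) {
    spec <- psm_spec(half_cycle = half)
    accumulate(membership(spec, bm$os_tis, bm$pfs_tis), econ, spec)$total_qaly
  }
  q_end <- run(FALSE); q_mid <- run(TRUE)
  expect_gt(q_mid, q_end)          # survival is non-increasing
  expect_lt(q_mid / q_end - 1, 0.02)
})

test_that("ICER arithmetic, dominance flags and currency guard", {
  mk <- function(cost, qaly, currency = "USD")
    list(total_cost = cost, total_qaly = qaly, currency = currency)
  r <- icer(mk(12995.39, 2.146), mk(0, 2.146 - 0.568))
  expect_equal(r$icer, 12995.39 / 0.568, tolerance = 1e-10)
  expect_equal(round(r$icer, 2), 22879.21)
  expect_equal(r$flag, "icer")
  expect_equal(icer(mk(-1, 1.1), mk(0, 1))$flag, "dominant")
  expect_equal(icer(mk(1, 0.9), mk(0, 1))$flag, "dominated")
  r0 <- icer(mk(10, 1), mk(10, 0.5))
  expect_equal(r0$icer, 0)
  rna <- icer(mk(10, 1), mk(5, 1))
  expect_equal(rna$flag, "undefined")
  expect_true(is.na(rna$icer))
  expect_error(icer(mk(10, 1, "USD"), mk(5, 0.5, "CNY")), "currencies")
})

test_that("net monetary benefit is wtp * dQALY - dCost", {
  r <- list(delta_cost = 12995.39, delta_qaly = 0.568)
  expect_equal(net_monetary_benefit(r, 37653), 37653 * 0.568 - 12995.39)
  expect_equal(round(net_monetary_benefit(r, 37653), 2), 8391.51)
  expect_equal(net_monetary_benefit(r, 0), -12995.39)
  expect_equal(net_monetary_benefit(r, 12995.39 / 0.568), 0, tolerance = 1e-9)
  expect_error(net_monetary_benefit(r, -1))
})
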