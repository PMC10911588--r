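test_that("default ranges reproduce the published lower/upper columns", {
  specs <- default_ranges(default_parameter_table())
  row <- function(key) specs[specs$key == key, ]
  tis <- row("cost_drug.tislelizumab")
  expect_equal(c(tis$base, tis$low, tis$high), c(192.85, 154.28, 231.42))
  ast <- row("risk_ae.ast_increased.tislelizumab")
  expect_equal(c(ast$base, ast$low, ast$high), c(0.231, 0.2079, 0.2541))
  upd <- row("utility.utility_pd")
  expect_equal(c(upd$base, upd$low, upd$high), c(0.68, 0.60, 0.68))
  # survival parameters are never varied
  expect_false(any(specs$category == "survival"))
  # keys are unique and alphabetically ordered (the fixed sampling order)
  expect_false(anyDuplicated(specs$key) > 0)
  expect_equal(specs$key, sort(specs$key))
  # rows lacking a printed range get the conventions applied
  tab <- default_parameter_table()
  i <- which(tab$category == "cost_drug" & tab$name == "sorafenib")
  tab$low[i] <- NA; tab$high[i] <- NA
  j <- which(tab$category == "risk_ae" & tab$name == "fatigue" &
               tab$arm == "tislelizumab")
  tab$low[j] <- NA; tab$high[j] <- NA
  sp2 <- default_ranges(tab)
  expect_equal(unlist(sp2[sp2$key == "cost_drug.sorafenib", c("low", "high")]),
               c(low = 3.19 * 0.8, high = 3.19 * 1.2))
  expect_equal(unlist(sp2[sp2$key == "risk_ae.fatigue.tislelizumab",
                          c("low", "high")]),
               c(low = 0.062 * 0.9, high = 0.062 * 1.1))
})

test_that("moment matching yields the textbook gamma and beta parameters", {
  g <- distribution_params(100, 100 - 1.96 * 20, 100 + 1.96 * 20, "gamma")
  expect_equal(g$shape, 25, tolerance = 1e-12)
  expect_equal(g$scale, 4, tolerance = 1e-12)
  se <- sqrt(0.05)
  b <- distribution_params(0.5, 0.5 - 1.96 * se, 0.5 + 1.96 * se, "beta")
  expect_equal(b$alpha, 2, tolerance = 1e-12)
  expect_equal(b$beta, 2, tolerance = 1e-12)
  expect_error(distribution_params(1.5, 1, 2, "beta"), "in \\(0, 1\\)")
  # zero-width range collapses to the base value
  expect_equal(distribution_params(5, 5, 5, "gamma")$distribution, "fixed")
})

test_that("sampled distributions are mean-matched to the base value", {
  set.seed(91)
  specs <- default_ranges(default_parameter_table())
  for (key in c("cost_drug.camrelizumab", "utility.utility_pd",
                "risk_ae.diarrhea.sorafenib")) {
    row <- specs[specs$key == key, ]
    draws <- replicate(20000, psmcea:::.sample_param(row))
    expect_equal(mean(draws), row$base, tolerance = 0.01)
  }
})

test_that("tornado swings match manual double runs and degenerate to zero", {
  cfg <- default_config()
  specs <- default_ranges(cfg$table)
  upd <- specs[specs$key == "utility.utility_pd", ]
  tor <- owsa(cfg, upd)
  manual <- vapply(c(upd$low, upd$high), function(v) {
    tab <- cfg$table
    tab$value[tab$category == "utility" & tab$name == "utility_pd"] <- v
    psmcea:::cea_run(cfg, tab)$icer$icer
  }, numeric(1))
  expect_equal(c(tor$icer_low, tor$icer_high), manual, tolerance = 1e-12)
  expect_equal(tor$swing, abs(manual[2] - manual[1]), tolerance = 1e-12)
  # collapsed ranges give zero swing everywhere
  collapsed <- specs
  collapsed$low <- collapsed$base; collapsed$high <- collapsed$base
  tor0 <- owsa(cfg, collapsed)
  expect_equal(tor0$swing, rep(0, nrow(tor0)))
  expect_false(any(tor0$failed))
})

test_that("tornado entries come sorted by descending swing", {
  cfg <- default_config()
  specs <- default_ranges(cfg$table)
  tor <- owsa(cfg, specs[grepl("cost_drug", specs$key), ])
  expect_equal(tor$swing, sort(tor$swing, decreasing = TRUE))
})

test_that("a degenerate PSA with fixed parameters reproduces the base case", {
  cfg <- default_config()
  specs <- default_ranges(cfg$table)
  specs$distribution <- "fixed"
  psa <- run_psa(cfg, specs, n_draws = 3, seed = 1)
  bc <- base_case(cfg)
  expect_equal(psa$draws$delta_cost, rep(bc$icer$delta_cost, 3), tolerance = 1e-12)
  expect_equal(psa$draws$delta_qaly, rep(bc$icer$delta_qaly, 3), tolerance = 1e-12)
})

test_that("PSA is bit-reproducible for a fixed seed", {
  cfg <- default_config()
  p1 <- run_psa(cfg, n_draws = 25, seed = 2024)
  p2 <- run_psa(cfg, n_draws = 25, seed = 2024)
  expect_identical(p1$draws, p2$draws)
  expect_identical(ceac(p1, seq(0, 50000, 500)), ceac(p2, seq(0, 50000, 500)))
  p3 <- run_psa(cfg, n_draws = 25, seed = 2025)
  expect_false(identical(p1$draws, p3$draws))
})

test_that("PSA draw means converge to the base case", {
  cfg <- default_config()
  bc <- base_case(cfg)
  psa <- run_psa(cfg, n_draws = 400, seed = 7)
  for (col in c("delta_cost", "delta_qaly")) {
    x <- psa$draws[[col]]
    base <- if (col == "delta_cost") bc$icer$delta_cost else bc$icer$delta_qaly
    se <- stats::sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - base), 3 * se)
  }
})

test_that("the acceptability curve has the right limits and is monotone", {
  cfg <- default_config()
  psa <- run_psa(cfg, n_draws = 150, seed = 5)
  expect_true(all(psa$draws$delta_cost > 0))   # intervention always costlier
  expect_true(all(psa$draws$delta_qaly > 0))
  cc <- ceac(psa, seq(0, 60000, 250))
  expect_equal(cc$probability[cc$wtp == 0], 0)
  expect_equal(cc$probability[cc$wtp == 60000], 1)
  expect_true(all(diff(cc$probability) >= 0))
  cross <- ceac_crossing(cc, 0.5)
  expect_true(cross > 15000 && cross < 35000)
  # at 3x per-capita GDP essentially every draw is cost-effective
  p_3gdp <- mean(37653 * psa$draws$delta_qaly - psa$draws$delta_cost > 0)
  expect_gte(p_3gdp, 0.95)
})

test_that("the crossing interpolates between grid points", {
  fake <- data.frame(wtp = c(0, 100, 200), probability = c(0, 0.25, 0.75))
  expect_equal(ceac_crossing(fake, 0.5), 150)
  expect_equal(ceac_crossing(fake, 0.75), 200)
  expect_true(is.na(ceac_crossing(fake, 0.9)))
})

test_that("discount-rate scenarios bracket the base case in order", {
  cfg <- default_config()
  sc <- scenario_discount(cfg, c(0.03, 0.05, 0.08))
  bc <- base_case(cfg)
  expect_equal(sc$icer[sc$rate == 0.05], bc$icer$icer, tolerance = 1e-12)
  expect_true(sc$icer[1] < sc$icer[2] && sc$icer[2] < sc$icer[3])
  expect_error(scenario_discount(cfg, 0.1), "0.08")
})

test_that("undiscounted scenario matches a quadrature-built ICER", {
  cfg <- default_config()
  sc0 <- psmcea:::cea_run(cfg, spec = psm_spec(discount = 0))
  H <- cfg$spec$n_cycles * 21 / 30.4375
  quad_arm <- function(arm) {
    m <- cfg$models[[arm]]
    econ <- build_arm_economics(cfg$table, arm)
    occ <- function(t, what) {
      s_os <- surv_prob(m$os, t); s_pfs <- pmin(surv_prob(m$pfs, t), s_os)
      switch(what, pfs = s_pfs, pd = s_os - s_pfs, os = s_os)
    }
    q <- stats::integrate(function(t)
      (occ(t, "pfs") * 0.76 + occ(t, "pd") * 0.68) / 12, 0, H,
      rel.tol = 1e-9, subdivisions = 2000)$value
    cost <- econ$one_off_ae_cost + stats::integrate(function(t)
      (occ(t, "pfs") * econ$c_pfs_cycle + occ(t, "pd") * econ$c_pd_cycle +
         occ(t, "os") * econ$c_followup) / (21 / 30.4375), 0, H,
      rel.tol = 1e-9, subdivisions = 2000)$value
    c(q = q, cost = cost)
  }
  a1 <- quad_arm(cfg$arms[1]); a2 <- quad_arm(cfg$arms[2])
  icer_quad <- (a1["cost"] - a2["cost"]) / (a1["q"] - a2["q"])
  expect_equal(sc0$icer$icer, unname(icer_quad), tolerance = 0.02)
})
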