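test_that("discounting is exponential with an undiscounted first cycle", {
  expect_equal(discount_factor(1, 0.03, 0.25), 1)
  expect_equal(discount_factor(7, 0, 0.25), 1)
  expect_equal(discount_factor(2, 0.03, 0.25), 0.992638, tolerance = 1e-6)
  # discounted totals never exceed undiscounted ones
  k <- 1:8
  expect_true(all(discount_factor(k, 0.05, 0.25) <= 1))
})

test_that("QALY accrual is utility x time on post-transition occupancy", {
  tr <- run_trace(c(1, 0, 0, 0, 0, 0), transition_matrix(diag(6), "id"), 1)
  u <- utility_set("x", c(0.778, 0.732, 0.681, 0.635, 0.595, 0.553),
                   rep(0.01, 6))
  expect_equal(accrue_qalys(tr, u, annual_rate = 0), 0.778 * 0.25)
  expect_equal(accrue_qalys(tr, rep(0.5, 6) * 0 + 1e-12, annual_rate = 0),
               1e-12 * 0.25)
})

test_that("raising any band utility never lowers total QALYs", {
  set.seed(11)
  tr <- run_trace(random_simplex(),
                  transition_matrix(random_stochastic(), "x"), 2)
  u <- runif(6, 0.4, 0.8)
  base <- accrue_qalys(tr, u)
  for (b in 1:6) {
    up <- u; up[b] <- up[b] + 0.05
    expect_gte(accrue_qalys(tr, up), base)
  }
})

test_that("drug-only cost accrual matches dose price times cycles", {
  tm <- transition_matrix(diag(6), "id")
  tr <- run_trace(c(0, 1, 0, 0, 0, 0), tm, 2)
  cs <- zero_costs(drug = 1708)
  undisc <- accrue_costs(tr, cs, drug_active = TRUE, annual_rate = 0)
  expect_equal(undisc$total, 2 * 1708)
  expect_equal(unname(undisc$items[c("administration", "medication",
                                     "diagnostics")]), c(0, 0, 0))
  # placebo with everything zeroed costs nothing
  expect_equal(accrue_costs(tr, zero_costs(), drug_active = FALSE)$total, 0)
})

test_that("with non-drug costs shared, the arm difference is the drug cost", {
  m <- base_model()
  cs <- zero_costs(drug = m$costs$drug_cost_per_dose, admin = 203,
                   diag_cost = 400, diag_prob = 0.5)
  tr_e <- run_trace(m$init, m$strategies$eptinezumab$tm, 2)
  tr_p <- run_trace(m$init, m$strategies$placebo$tm, 2)
  ce <- accrue_costs(tr_e, cs, TRUE)$total
  cp <- accrue_costs(tr_p, cs, FALSE)$total
  expect_equal(ce - cp,
               sum(discount_factor(1:2) * m$costs$drug_cost_per_dose))
})

test_that("chronicity-dependent medication costs follow the occupancy", {
  cs <- zero_costs(cm_acute = 270, cm_prev = 37, em_acute = 184,
                   em_prev = 27.4)
  tm <- transition_matrix(diag(6), "id")
  cm_arm <- run_trace(c(0, 0, 0, 0, 1, 0), tm, 2) # stays chronic
  em_arm <- run_trace(c(0, 1, 0, 0, 0, 0), tm, 2) # stays episodic
  expect_equal(accrue_costs(cm_arm, cs, FALSE, annual_rate = 0)$total,
               2 * (270 + 37))
  expect_equal(accrue_costs(em_arm, cs, FALSE, annual_rate = 0)$total,
               2 * (184 + 27.4))
})

test_that("ICER sign conventions cover all four quadrants", {
  expect_equal(compute_icer(c(200, 100), c(2, 1))$icer, 100)
  expect_equal(compute_icer(c(100, 200), c(2, 1))$status, "dominant")
  expect_equal(compute_icer(c(200, 100), c(1, 2))$status, "dominated")
  # less costly and less effective: a defined (southwest) ICER
  sw <- compute_icer(c(100, 200), c(1, 2))
  expect_equal(sw$status, "icer")
  expect_equal(sw$icer, 100)
  # zero QALY difference never throws, it flags
  expect_equal(compute_icer(c(200, 100), c(1, 1))$status, "dominated")
  expect_equal(compute_icer(c(100, 200), c(1, 1))$status, "dominant")
  expect_equal(compute_icer(c(100, 100), c(1, 1))$status, "undefined")
  expect_true(is.na(compute_icer(c(200, 100), c(1, 1))$icer))
})

test_that("net monetary benefit and its threshold identity hold", {
  expect_equal(net_monetary_benefit(0, 0, 50000), 0)
  expect_equal(net_monetary_benefit(1065, 0.31, 96981),
               96981 * 0.31 - 1065)
  # NMB favours the intervention iff wtp exceeds the ICER (when dE > 0)
  ce <- solve_model(base_model())$ce
  for (wtp in c(32327, 73000, 75000, 96981)) {
    favours <- net_monetary_benefit(ce$summary$cost[1], ce$summary$qalys[1], wtp) >
      net_monetary_benefit(ce$summary$cost[2], ce$summary$qalys[2], wtp)
    expect_equal(favours, wtp > ce$icer)
  }
})

test_that("utility and cost inputs are validated", {
  expect_error(utility_set("x", c(1.2, rep(0.5, 5)), rep(0.01, 6)), "\\(0, 1\\)")
  expect_error(utility_set("x", rep(0.5, 6), c(0.6, rep(0.01, 5))),
               "too large")
  expect_error(zero_costs(drug = -1), ">= 0")
  expect_error(beta_moments(0.778, 0.5, "u"), "too large")
  expect_equal(gamma_moments(270, 135)[["shape"]], 4)
})
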