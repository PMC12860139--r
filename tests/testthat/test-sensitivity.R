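test_that("parameters shared by both arms leave the ICER untouched", {
  m <- base_model()
  base_icer <- solve_model(m)$ce$icer
  torn <- run_owsa(m, default_owsa_specs(m)[
    default_owsa_specs(m)$type %in% c("admin", "diagnostics"), ])
  expect_equal(torn$icer_low, rep(base_icer, 2))
  expect_equal(torn$icer_high, rep(base_icer, 2))
  expect_equal(torn$width, rep(0, 2))
})

test_that("tornado entries are sorted by width, utilities on top", {
  m <- base_model()
  torn <- run_owsa(m)
  expect_true(all(diff(torn$width[!is.na(torn$width)]) <= 0))
  expect_equal(torn$type[1], "utility")
  # lowering the intervention's utility raises the ICER and vice versa
  row <- torn[torn$parameter == "utility eptinezumab, 4-9 MMDs", ]
  expect_gt(row$icer_low, attr(torn, "base_icer"))
  expect_lt(row$icer_high, attr(torn, "base_icer"))
})

test_that("an arm-specific cost moves the ICER oppositely across arms", {
  m <- base_model()
  base_icer <- solve_model(m)$ce$icer
  spec_e <- data.frame(id = "admin ept", type = "admin", arm = "eptinezumab",
                       band = NA, from = NA, to = NA, item = NA,
                       low = 0.8, high = 1.2)
  spec_p <- spec_e; spec_p$arm <- "placebo"
  up_e <- solve_model(perturb_model(m, spec_e, 1.2))$ce$icer - base_icer
  up_p <- solve_model(perturb_model(m, spec_p, 1.2))$ce$icer - base_icer
  expect_gt(up_e, 0)
  expect_lt(up_p, 0)
  expect_equal(up_e, -up_p, tolerance = 1e-9)
})

test_that("transition perturbations renormalize and cannot empty a row", {
  m <- base_model()
  spec <- data.frame(id = "t", type = "transition", arm = "placebo",
                     band = NA, from = "10-14", to = "4-9", item = NA,
                     low = 0.9, high = 1.1)
  m2 <- perturb_model(m, spec, 1.1)
  expect_equal(unname(rowSums(m2$strategies$placebo$tm$p)), rep(1, 6))
  expect_gt(m2$strategies$placebo$tm$p["10-14", "4-9"],
            m$strategies$placebo$tm$p["10-14", "4-9"])
})

test_that("degenerate distributions make every PSA draw the base case", {
  m <- degenerate_model()
  sol <- solve_model(m)
  one <- run_psa(m, n = 1, seed = 6)
  expect_equal(one$summary$mean_dc, sol$ce$incremental_cost, tolerance = 1e-12)
  expect_equal(one$summary$mean_de, sol$ce$incremental_qalys, tolerance = 1e-12)
  psa <- run_psa(m, n = 5, seed = 123)
  for (s in names(m$strategies)) {
    expect_equal(psa$draws[[paste0("cost_", s)]], rep(sol$total_cost[[s]], 5),
                 tolerance = 1e-12)
    expect_equal(psa$draws[[paste0("qaly_", s)]], rep(sol$qalys[[s]], 5),
                 tolerance = 1e-12)
  }
  expect_equal(psa$summary$mean_dc, sol$ce$incremental_cost, tolerance = 1e-12)
  expect_equal(psa$summary$mean_de, sol$ce$incremental_qalys, tolerance = 1e-12)
})

test_that("sampled distributions match their stated moments", {
  set.seed(99)
  b <- beta_moments(0.778, 0.010)
  x <- stats::rbeta(10000, b[1], b[2])
  expect_equal(mean(x), 0.778, tolerance = 0.005)
  g <- gamma_moments(270, 135)
  y <- stats::rgamma(10000, shape = g[1], rate = g[2])
  expect_equal(mean(y), 270, tolerance = 5 / 270)
  expect_equal(stats::sd(y), 135, tolerance = 0.05)
})

test_that("Dirichlet rows stay on the simplex with matched spread", {
  mean <- c(0, 0.29, 0.71, 0, 0, 0)
  se <- c(0, 0.03, 0.03, 0, 0, 0)
  nu <- dirichlet_concentration(mean, se)
  set.seed(5)
  rows <- rdirichlet_row(5000, mean, nu)
  expect_equal(unname(rowSums(rows)), rep(1, 5000), tolerance = 1e-12)
  expect_true(all(rows[, c(1, 4:6)] == 0)) # structural zeros preserved
  expect_equal(mean(rows[, 2]), 0.29, tolerance = 0.01)
  expect_equal(stats::sd(rows[, 2]), 0.03, tolerance = 0.005)
})

test_that("PSA is bit-reproducible under a fixed seed", {
  m <- base_model()
  p1 <- run_psa(m, n = 50, seed = 31)
  p2 <- run_psa(m, n = 50, seed = 31)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$summary, p2$summary)
})

test_that("the CEAC is complementary and monotone when all dE > 0", {
  m <- base_model()
  psa <- run_psa(m, n = 400, seed = 17)
  grid <- seq(0, 150000, by = 5000)
  cc <- ceac(psa, grid)
  expect_true(all(cc$p_eptinezumab >= 0 & cc$p_eptinezumab <= 1))
  expect_equal(cc$p_eptinezumab + cc$p_placebo, rep(1, nrow(cc)))
  if (all(psa$draws$de > 0)) {
    expect_true(all(diff(cc$p_eptinezumab) >= 0))
  }
  # at wtp 0 the probability is the fraction of cost-saving draws
  expect_equal(cc$p_eptinezumab[1], mean(psa$draws$dc < 0))
  # the curve crosses 0.5 near the median draw-level ICER (brute force)
  med <- stats::median(psa$draws$dc / psa$draws$de)
  crossing <- grid[min(which(cc$p_eptinezumab >= 0.5))]
  expect_lt(abs(crossing - med), 5000 + 1e-9)
  expect_error(ceac(psa, numeric(0)), "empty")
})
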