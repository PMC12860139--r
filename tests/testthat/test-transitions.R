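test_that("published column-oriented tables are transposed and renormalized", {
  tm <- from_table1(printed_ept, "eptinezumab")
  # the "24+" printed column sums to 1.01; its row is the column / 1.01
  col <- printed_ept[, 6]
  expect_equal(unname(tm$p["24+", ]), col / sum(col))
  # an exactly-summing column passes through unchanged
  tp <- from_table1(printed_pla, "placebo")
  expect_equal(unname(tp$p["4-9", ]), printed_pla[, 2])
  # identity in, identity out
  expect_equal(unname(from_table1(diag(6), "id")$p), diag(6))
})

test_that("renormalized rows sum to 1 and sit within rounding slack of print", {
  for (printed in list(printed_ept, printed_pla)) {
    tm <- from_table1(printed, "x")
    expect_equal(unname(rowSums(tm$p)), rep(1, 6), tolerance = 1e-12)
    expect_lt(max(abs(tm$p - t(printed))), 0.01)
  }
})

test_that("mis-keyed tables are rejected", {
  bad <- printed_ept
  bad[1, 2] <- 0.66 # column sums to 1.10
  expect_error(from_table1(bad, "x"), "mis-keyed")
  expect_error(from_table1(printed_ept - 2, "x"), "\\[0, 1\\]")
  expect_error(transition_matrix(matrix(0.5, 6, 6), "x"), "sum to 1")
})

test_that("cohort trace follows the matrix and conserves the cohort", {
  # all mass in 4-9 under placebo for one cycle splits 0.29 / 0.71
  tm <- from_table1(printed_pla, "placebo")
  tr <- run_trace(c(0, 1, 0, 0, 0, 0), tm, 1)
  expect_equal(unname(tr$occupancy[2, 1:2]), c(0.29, 0.71))
  # the 0-3 state is absorbing under both arms
  for (printed in list(printed_ept, printed_pla)) {
    tr <- run_trace(c(1, 0, 0, 0, 0, 0), from_table1(printed, "x"), 5)
    expect_equal(unname(tr$occupancy[, 1]), rep(1, 6))
  }
  # identity matrix leaves occupancy constant
  init <- random_simplex()
  tr <- run_trace(init, transition_matrix(diag(6), "id"), 3)
  expect_equal(unname(tr$occupancy[4, ]), init)
})

test_that("trace equals multiplication by the k-th matrix power (oracle)", {
  set.seed(101)
  for (rep in 1:10) {
    p <- random_stochastic()
    init <- random_simplex()
    tr <- run_trace(init, transition_matrix(p, "x"), 4)
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, 5), tolerance = 1e-9)
    pk <- diag(6)
    for (k in 1:4) {
      pk <- pk %*% p
      expect_equal(unname(tr$occupancy[k + 1, ]),
                   as.numeric(init %*% pk), tolerance = 1e-12)
    }
  }
})

test_that("expected MMD weights occupancy by band-representative values", {
  # stationary cohort at the 4-9 midpoint
  tr <- run_trace(c(0, 1, 0, 0, 0, 0), transition_matrix(diag(6), "id"), 2)
  em <- expected_mmd(tr)
  expect_equal(unname(em$per_cycle), rep(6.5, 3))
  expect_equal(em$change_from_baseline, 0)
  # a cohort moving 20-24 (22) -> 10-14 (12) in one step changes by 10
  p <- diag(6); p[5, 5] <- 0; p[5, 3] <- 1
  tr <- run_trace(c(0, 0, 0, 0, 1, 0), transition_matrix(p, "x"), 1)
  em <- expected_mmd(tr, band_values = c(1.5, 6.5, 12, 17, 22, 26))
  expect_equal(em$change_from_baseline, 10)
  # out-of-band representative values warn
  expect_warning(expected_mmd(tr, band_values = c(5, 6.5, 12, 17, 21.5, 26)),
                 "outside")
})

test_that("the default initial distribution reflects the trial mixture", {
  init <- initial_distribution()
  expect_equal(sum(init), 1, tolerance = 1e-12)
  expect_equal(unname(init[1]), 0) # trial entry requires >= 4 MMDs
  # sampling converges to the analytic integral
  init_s <- initial_distribution(method = "sample", n = 2e5, seed = 7)
  expect_equal(unname(init_s), unname(init), tolerance = 0.01)
  # roughly half the mixed cohort is chronic (baseline means 10/20.4/14.5)
  expect_gt(sum(init[4:6]), 0.3)
  expect_lt(sum(init[4:6]), 0.7)
})
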