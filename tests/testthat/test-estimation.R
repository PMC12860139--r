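make_panel <- function(baseline, c1, c2 = NULL, arm = "a") {
  df <- data.frame(patient_id = paste0("p", seq_along(baseline)),
                   arm = arm, baseline_mmd = baseline, mmd_c1 = c1)
  if (!is.null(c2)) df$mmd_c2 <- c2
  df
}

test_that("transitions are counted over consecutive banded pairs", {
  # one patient, baseline 20 -> cycle-1 MMD 8: one 20-24 -> 4-9 count
  cnt <- count_transitions(make_panel(20, 8), "a")
  expect_equal(sum(cnt), 1)
  expect_equal(cnt["20-24", "4-9"], 1)
  # baseline -> c1 and c1 -> c2 are pooled
  cnt <- count_transitions(make_panel(20, 8, 2), "a")
  expect_equal(sum(cnt), 2)
  expect_equal(cnt["4-9", "0-3"], 1)
  # constant-MMD patients count only on the diagonal
  cnt <- count_transitions(make_panel(c(5, 12, 25), c(5, 12, 25),
                                      c(5, 12, 25)), "a")
  expect_equal(sum(diag(cnt)), 6)
  expect_equal(sum(cnt) - sum(diag(cnt)), 0)
  expect_error(count_transitions(make_panel(5, 5), "other"), "no patients")
})

test_that("empirical proportions recover the generating matrix (LLN oracle)", {
  tm <- from_table1(printed_pla, "placebo")
  panel <- generate_cohort(list(placebo = tm), n_patients = 5000,
                           n_cycles = 2, seed = 501)
  cnt <- count_transitions(panel, "placebo")
  expect_gte(sum(cnt), 10000)
  prop <- cnt / rowSums(cnt)
  # binomial noise at 10,000 pooled transitions: compare well-filled rows
  observed <- rowSums(cnt) >= 1000
  expect_gte(sum(observed), 4)
  expect_lt(max(abs(prop[observed, ] - tm$p[observed, ])), 0.02)
})

test_that("single-resample and degenerate bootstraps have zero SE", {
  panel <- make_panel(c(20, 12, 6), c(8, 12, 4), c(4, 6, 4))
  est <- bootstrap_matrix(panel, "a", n_resamples = 1, seed = 1)
  expect_equal(est$mean, est$point)
  expect_true(all(est$se == 0))
  # identical patients: resampling cannot produce variation
  clones <- make_panel(rep(20, 8), rep(8, 8), rep(4, 8))
  est <- bootstrap_matrix(clones, "a", n_resamples = 200, seed = 2)
  expect_true(all(est$se == 0))
  expect_equal(est$mean["20-24", "4-9"], 1)
})

test_that("bootstrap mean converges to the sample proportions", {
  tm <- from_table1(printed_ept, "eptinezumab")
  panel <- generate_cohort(list(eptinezumab = tm), n_patients = 800,
                           n_cycles = 2, seed = 77)
  est <- bootstrap_matrix(panel, "eptinezumab", n_resamples = 5000, seed = 78)
  expect_lt(max(abs(est$mean - est$point)), 0.01)
  expect_equal(unname(rowSums(est$mean)), rep(1, 6), tolerance = 1e-12)
})

test_that("estimation is invariant to patient order and id relabeling", {
  tm <- from_table1(printed_pla, "placebo")
  panel <- generate_cohort(list(placebo = tm), n_patients = 120,
                           n_cycles = 2, seed = 9)
  shuffled <- panel[sample(nrow(panel)), ]
  shuffled$patient_id <- paste0("z", seq_len(nrow(shuffled)))
  expect_equal(count_transitions(shuffled, "placebo"),
               count_transitions(panel, "placebo"))
  e1 <- bootstrap_matrix(panel, "placebo", 300, seed = 10)
  e2 <- bootstrap_matrix(shuffled, "placebo", 300, seed = 10)
  expect_equal(e1$point, e2$point)
})

test_that("a from-band never observed falls back to self-transition", {
  # nobody ever occupies 24+: its estimated row must still be stochastic
  panel <- make_panel(c(6, 12), c(4, 10))
  est <- bootstrap_matrix(panel, "a", n_resamples = 50, seed = 3)
  expect_equal(est$mean["24+", "24+"], 1)
  expect_equal(unname(rowSums(est$mean)), rep(1, 6))
})
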