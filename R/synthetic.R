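#' Generate a synthetic trial-like patient cohort
#'
#' Stands in for the (non-deposited) patient-level trial data: each patient
#' is assigned a trial by weight, a baseline MMD from that trial's scaled
#' Beta distribution on `support` (trial entry requires >= 4 MMDs), sex and
#' age sampled independently of MMD, and a 1:1 randomized arm allocation.
#' Each cycle the patient's band advances by the arm's transition row at
#' the current band, and a concrete MMD is drawn uniformly within the new
#' band (the open "24+" band uses \[24, 30\]).
#'
#' @param arm_matrices Named list of [transition_matrix()] objects, one per
#'   arm.
#' @param n_patients Cohort size (>= 1).
#' @param profiles A [trial_profiles()] data.frame.
#' @param n_cycles Number of follow-up cycles.
#' @param concentration Beta concentration for baseline MMDs.
#' @param support Baseline MMD range, default `c(4, 28)`.
#' @param seed Optional seed; a fixed seed yields a byte-identical panel.
#' @return Patient panel data.frame: `patient_id`, `trial`, `arm`, `age`,
#'   `female`, `baseline_mmd`, `mmd_c1` ... `mmd_cK`.
#' @export
generate_cohort <- function(arm_matrices, n_patients,
                            profiles = trial_profiles(), n_cycles = 2,
                            concentration = 10, support = c(4, 28),
                            seed = NULL) {
  stopifnot(n_patients >= 1, n_cycles >= 1, length(arm_matrices) >= 1)
  if (is.null(names(arm_matrices))) {
    stop("`arm_matrices` must be a named list (one matrix per arm)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  b <- mmd_bands()
  band_hi <- pmin(b$upper, 30) # concrete MMDs in the open band: [24, 30]

  comp <- sample.int(nrow(profiles), n_patients, replace = TRUE,
                     prob = profiles$weight)
  sh <- vapply(profiles$baseline_mmd_mean, scaled_beta_shapes, numeric(2L),
               concentration = concentration, support = support)
  baseline <- support[1L] + diff(support) *
    stats::rbeta(n_patients, sh[1L, comp], sh[2L, comp])
  baseline <- round(baseline, 2) # stored precision; band on what is stored
  female <- stats::rbinom(n_patients, 1L,
                          profiles$female_proportion[comp]) == 1L
  age <- pmin(pmax(stats::rnorm(n_patients, profiles$age_mean[comp],
                                profiles$age_sd[comp]), 18), 75)
  arms <- sample(rep(names(arm_matrices), length.out = n_patients))

  mmd <- matrix(NA_real_, n_patients, n_cycles)
  state <- band_index(band_of_mmd(baseline))
  for (k in seq_len(n_cycles)) {
    for (i in seq_len(n_patients)) {
      row <- arm_matrices[[arms[i]]]$p[state[i], ]
      state[i] <- sample.int(6L, 1L, prob = row)
    }
    mmd[, k] <- stats::runif(n_patients, b$lower[state], band_hi[state])
  }
  colnames(mmd) <- paste0("mmd_c", seq_len(n_cycles))

  data.frame(patient_id = sprintf("pt%05d", seq_len(n_patients)),
             trial = profiles$trial[comp],
             arm = arms,
             age = round(age, 1),
             female = female,
             baseline_mmd = baseline,
             round(as.data.frame(mmd), 2),
             stringsAsFactors = FALSE)
}

#' Read/write a patient panel as CSV
#'
#' @param panel A [generate_cohort()] data.frame.
#' @param path CSV file path.
#' @return `write_panel` invisibly returns `path`; `read_panel` returns the
#'   validated panel.
#' @export
write_panel <- function(panel, path) {
  check_panel(panel)
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_panel(panel)
  panel
}
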