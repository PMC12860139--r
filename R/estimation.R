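#' Patient-level longitudinal MMD panel helpers
#'
#' A panel is a data.frame with columns `patient_id`, `arm`, `baseline_mmd`,
#' `mmd_c1` ... `mmd_cK` and optional covariates (`age`, `female`).
#' @noRd
panel_mmd_columns <- function(panel) {
  cols <- grep("^mmd_c[0-9]+$", names(panel), value = TRUE)
  cols[order(as.integer(sub("^mmd_c", "", cols)))]
}

check_panel <- function(panel) {
  need <- c("patient_id", "arm", "baseline_mmd")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns ", paste(need, collapse = ", "),
         " and mmd_c1..mmd_cK", call. = FALSE)
  }
  cols <- panel_mmd_columns(panel)
  if (!length(cols)) stop("panel has no mmd_c<k> columns", call. = FALSE)
  vals <- as.matrix(panel[c("baseline_mmd", cols)])
  if (anyNA(vals) || any(vals < 0)) {
    stop("all MMD values must be present and >= 0", call. = FALSE)
  }
  cols
}

# per-patient 6x6 transition counts, flattened column-major to length 36
patient_transition_counts <- function(panel) {
  cols <- check_panel(panel)
  seq_bands <- apply(as.matrix(panel[c("baseline_mmd", cols)]), 2, band_of_mmd)
  if (is.null(dim(seq_bands))) seq_bands <- matrix(seq_bands, nrow = 1)
  n_steps <- length(cols)
  out <- matrix(0L, nrow(panel), 36L)
  for (k in seq_len(n_steps)) {
    from <- band_index(seq_bands[, k])
    to <- band_index(seq_bands[, k + 1L])
    cell <- (to - 1L) * 6L + from
    for (i in seq_len(nrow(panel))) {
      out[i, cell[i]] <- out[i, cell[i]] + 1L
    }
  }
  out
}

counts_to_matrix <- function(counts36) {
  m <- matrix(counts36, 6L, 6L,
              dimnames = list(from = band_labels(), to = band_labels()))
  m
}

# row-normalize a count matrix; a from-band with no observed departures
# falls back to self-transition with probability 1, keeping rows stochastic
row_normalize_counts <- function(cnt) {
  rs <- rowSums(cnt)
  p <- cnt / ifelse(rs == 0, 1, rs)
  empty <- which(rs == 0)
  for (i in empty) p[i, i] <- 1
  p
}

#' Pooled transition counts from a patient panel
#'
#' Pools every consecutive band pair (baseline to cycle 1, cycle k-1 to
#' cycle k) of the given arm into a 6x6 from/to count matrix, using
#' [band_of_mmd()] to band the observed MMD values. A single stationary
#' matrix per arm is assumed, matching the model's per-cycle transition
#' structure.
#'
#' @param panel Patient panel data.frame (see [generate_cohort()]).
#' @param arm Arm label to subset on.
#' @return 6x6 integer matrix of transition counts (row = from).
#' @export
count_transitions <- function(panel, arm) {
  panel <- panel[panel$arm == arm, , drop = FALSE]
  if (!nrow(panel)) stop("no patients in arm '", arm, "'", call. = FALSE)
  counts_to_matrix(colSums(patient_transition_counts(panel)))
}

#' Bootstrap estimate of an arm's transition matrix
#'
#' Resamples patients (not individual transitions) with replacement,
#' preserving within-patient correlation across cycles; each resample
#' yields a row-normalized proportion matrix, and the estimate is the
#' elementwise mean with the elementwise standard deviation across
#' resamples as the standard error. Rows of the mean are renormalized to
#' sum to 1.
#'
#' @param panel Patient panel data.frame.
#' @param arm Arm label.
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param seed Optional seed for reproducibility.
#' @return Object of class `bootstrap_estimate`: `mean` (row-stochastic
#'   6x6), `se` (6x6), `point` (no-resampling proportion matrix),
#'   `n_resamples`, `n_patients`.
#' @export
bootstrap_matrix <- function(panel, arm, n_resamples = 1000, seed = NULL) {
  panel <- panel[panel$arm == arm, , drop = FALSE]
  if (!nrow(panel)) stop("arm '", arm, "' absent from panel", call. = FALSE)
  stopifnot(n_resamples >= 1)
  if (!is.null(seed)) set.seed(seed)
  C <- patient_transition_counts(panel)
  n <- nrow(C)
  point <- row_normalize_counts(counts_to_matrix(colSums(C)))

  if (n_resamples == 1L) {
    props <- matrix(as.vector(point), 1L, 36L)
  } else {
    props <- matrix(NA_real_, n_resamples, 36L)
    for (b in seq_len(n_resamples)) {
      idx <- sample.int(n, n, replace = TRUE)
      cnt <- counts_to_matrix(colSums(C[idx, , drop = FALSE]))
      props[b, ] <- as.vector(row_normalize_counts(cnt))
    }
  }
  mean_m <- counts_to_matrix(colMeans(props))
  mean_m <- mean_m / rowSums(mean_m)
  se_m <- counts_to_matrix(apply(props, 2, stats::sd))
  if (n_resamples == 1L) se_m[] <- 0
  structure(list(mean = mean_m, se = se_m, point = point,
                 n_resamples = as.integer(n_resamples), n_patients = n),
            class = "bootstrap_estimate")
}
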