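#' Construct a validated transition matrix
#'
#' Internal convention throughout the package is row-stochastic: row = from
#' band, column = to band, each row summing to 1.
#'
#' @param p 6x6 numeric matrix of transition probabilities (row = from).
#' @param strategy Strategy identifier (e.g. `"eptinezumab"`).
#' @param se Optional 6x6 matrix of standard errors.
#' @param normalize If `TRUE`, renormalize each row to sum to 1 before
#'   validating (rows must already sum to within 5% of 1).
#' @return An object of class `transition_matrix`: list with elements `p`,
#'   `se`, `strategy`.
#' @export
transition_matrix <- function(p, strategy, se = NULL, normalize = FALSE) {
  p <- as.matrix(p)
  if (!all(dim(p) == c(6L, 6L))) {
    stop("transition matrix must be 6x6", call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) {
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(p)
  if (normalize) {
    if (any(abs(rs - 1) > 0.05)) {
      stop("row sums outside [0.95, 1.05]; matrix looks mis-keyed", call. = FALSE)
    }
    p <- p / rs
  } else if (any(abs(rs - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1 (use normalize = TRUE for ",
         "rounded published tables)", call. = FALSE)
  }
  dimnames(p) <- list(from = band_labels(), to = band_labels())
  if (!is.null(se)) {
    se <- as.matrix(se)
    if (!all(dim(se) == c(6L, 6L)) || any(se < 0)) {
      stop("`se` must be a 6x6 matrix of non-negative standard errors",
           call. = FALSE)
    }
    dimnames(se) <- dimnames(p)
  }
  structure(list(p = p, se = se, strategy = strategy),
            class = "transition_matrix")
}

#' Ingest a published column-oriented transition table
#'
#' The published table is column-stochastic (columns = from-state,
#' rows = to-state) and carries rounding error: some columns sum to 0.99 or
#' 1.01 rather than 1. This transposes to the package's row-stochastic
#' convention and renormalizes each row so it sums exactly to 1.
#'
#' @param column_major 6x6 matrix as printed: entry `[i, j]` is the
#'   probability of moving from band `j` to band `i`.
#' @param strategy Strategy identifier.
#' @return A [transition_matrix()].
#' @export
from_table1 <- function(column_major, strategy) {
  m <- as.matrix(column_major)
  if (!all(dim(m) == c(6L, 6L))) {
    stop("printed transition table must be 6x6", call. = FALSE)
  }
  if (any(m < 0) || any(m > 1)) {
    stop("printed probabilities must lie in [0, 1]", call. = FALSE)
  }
  cs <- colSums(m)
  bad <- which(cs < 0.95 | cs > 1.05)
  if (length(bad)) {
    stop("printed column(s) ", paste(band_labels()[bad], collapse = ", "),
         " sum to ", paste(round(cs[bad], 3), collapse = ", "),
         "; outside [0.95, 1.05] - table looks mis-keyed", call. = FALSE)
  }
  transition_matrix(t(m), strategy = strategy, normalize = TRUE)
}

#' Run the deterministic Markov cohort trace
#'
#' The cohort transitions at the beginning of each cycle; row `k + 1` of the
#' trace is the occupancy during cycle `k` (post-transition). Row 1 is the
#' initial distribution. No mortality: occupancy is conserved.
#'
#' @param init Numeric 6-vector of initial state occupancy (sums to 1).
#' @param tm A [transition_matrix()].
#' @param n_cycles Number of cycles (>= 1); the base case uses 2 quarterly
#'   cycles over six months.
#' @return An object of class `cohort_trace`: list with `occupancy`
#'   ((n_cycles + 1) x 6 matrix), `n_cycles`.
#' @export
run_trace <- function(init, tm, n_cycles = 2) {
  stopifnot(inherits(tm, "transition_matrix"))
  init <- as.numeric(init)
  if (length(init) != 6L || any(init < 0) || abs(sum(init) - 1) > 1e-9) {
    stop("`init` must be a non-negative 6-vector summing to 1", call. = FALSE)
  }
  if (n_cycles < 1) stop("`n_cycles` must be >= 1", call. = FALSE)
  occ <- matrix(NA_real_, n_cycles + 1L, 6L,
                dimnames = list(cycle = 0:n_cycles, band = band_labels()))
  occ[1L, ] <- init
  for (k in seq_len(n_cycles)) {
    occ[k + 1L, ] <- occ[k, ] %*% tm$p
  }
  structure(list(occupancy = occ, n_cycles = as.integer(n_cycles)),
            class = "cohort_trace")
}

#' Expected MMD per cycle and change from baseline
#'
#' Occupancy-weighted mean monthly migraine days at baseline and at each
#' cycle, plus the change from baseline to the final cycle.
#'
#' @param trace A [run_trace()] result.
#' @param band_values Representative MMD per band; defaults to
#'   [band_midpoints()]. A warning is issued if any value falls outside its
#'   band's integer range.
#' @return List with `per_cycle` (length n_cycles + 1, baseline first) and
#'   `change_from_baseline` (baseline mean minus final-cycle mean).
#' @export
expected_mmd <- function(trace, band_values = band_midpoints()) {
  stopifnot(inherits(trace, "cohort_trace"))
  band_values <- as.numeric(band_values)
  if (length(band_values) != 6L) {
    stop("`band_values` must have length 6", call. = FALSE)
  }
  b <- mmd_bands()
  # half-unit slack: fractional values still rounding into the band are fine
  out_of_band <- band_values < b$lower - 0.5 | band_values > b$upper + 0.5
  if (any(out_of_band)) {
    warning("band value(s) for ", paste(b$label[out_of_band], collapse = ", "),
            " lie outside the band's MMD range", call. = FALSE)
  }
  per_cycle <- as.numeric(trace$occupancy %*% band_values)
  names(per_cycle) <- rownames(trace$occupancy)
  list(per_cycle = per_cycle,
       change_from_baseline = per_cycle[[1L]] - per_cycle[[length(per_cycle)]])
}
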