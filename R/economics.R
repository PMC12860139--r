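#' Per-arm utility set
#'
#' State- and arm-specific preference weights (MSQ-derived EQ-5D-3L values
#' for an Asian anti-CGRP trial population), strictly decreasing in MMD
#' severity within each arm.
#'
#' @param strategy Strategy identifier.
#' @param mean Numeric 6-vector of mean utilities in (0, 1), one per band.
#' @param sd Numeric 6-vector of standard deviations (> 0 allowed to be 0
#'   for a deterministic analysis).
#' @return Object of class `utility_set`.
#' @export
utility_set <- function(strategy, mean, sd) {
  mean <- as.numeric(mean); sd <- as.numeric(sd)
  if (length(mean) != 6L || length(sd) != 6L) {
    stop("utilities need one mean and sd per band", call. = FALSE)
  }
  if (any(mean <= 0) || any(mean >= 1)) {
    stop("utility means must lie in (0, 1)", call. = FALSE)
  }
  if (any(sd < 0)) stop("utility sds must be >= 0", call. = FALSE)
  for (i in which(sd > 0)) {
    beta_moments(mean[i], sd[i], paste0("utility ", band_labels()[i]))
  }
  structure(list(strategy = strategy,
                 mean = stats::setNames(mean, band_labels()),
                 sd = stats::setNames(sd, band_labels())),
            class = "utility_set")
}

#' Cost schedule shared by both arms
#'
#' Per-cycle medication costs depend on the chronicity of the current band
#' (CM bands accrue CM acute + prevention costs, EM bands EM costs); the
#' drug and an administration fee accrue once per infusion cycle; a one-time
#' expected diagnostic work-up (sum of unit cost x use probability) accrues
#' at model entry.
#'
#' @param drug_cost_per_dose Acquisition cost per dose (USD).
#' @param doses_per_cycle Doses per model cycle.
#' @param drug_uniform_halfwidth Half-width (as a fraction of the mean) of
#'   the Uniform distribution used for the drug cost in probabilistic
#'   analyses.
#' @param admin_cost_per_infusion Administration cost per infusion visit,
#'   accrued by both arms each cycle. May be a single value or a named
#'   vector per strategy.
#' @param medication data.frame with columns `item`
#'   (cm_acute, cm_prevention, em_acute, em_prevention), `mean`, `sd`; USD
#'   per cycle.
#' @param diagnostics data.frame with columns `item`, `unit_cost`, `sd`,
#'   `use_prob`; one-time entry costs.
#' @return Object of class `cost_schedule`.
#' @export
cost_schedule <- function(drug_cost_per_dose = 1708,
                          doses_per_cycle = 1L,
                          drug_uniform_halfwidth = 0.2,
                          admin_cost_per_infusion = 0,
                          medication,
                          diagnostics) {
  stopifnot(is.data.frame(medication), is.data.frame(diagnostics))
  need <- c("cm_acute", "cm_prevention", "em_acute", "em_prevention")
  if (!setequal(medication$item, need)) {
    stop("`medication` must contain exactly the items: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.null(diagnostics$sd)) diagnostics$sd <- 0
  vals <- c(drug_cost_per_dose, admin_cost_per_infusion,
            medication$mean, medication$sd,
            diagnostics$unit_cost, diagnostics$sd)
  if (any(vals < 0)) stop("costs and sds must be >= 0", call. = FALSE)
  if (any(diagnostics$use_prob < 0 | diagnostics$use_prob > 1)) {
    stop("diagnostic use probabilities must lie in [0, 1]", call. = FALSE)
  }
  medication <- medication[match(need, medication$item), , drop = FALSE]
  structure(list(drug_cost_per_dose = drug_cost_per_dose,
                 doses_per_cycle = as.integer(doses_per_cycle),
                 drug_uniform_halfwidth = drug_uniform_halfwidth,
                 admin_cost_per_infusion = admin_cost_per_infusion,
                 medication = medication,
                 diagnostics = diagnostics),
            class = "cost_schedule")
}

#' Per-cycle discount factor
#'
#' Exponential discounting at an annual rate; the first cycle is
#' undiscounted.
#'
#' @param cycle_index Cycle number, 1-based.
#' @param annual_rate Annual discount rate (0.03 in the base case).
#' @param cycle_length_years Cycle length as a fraction of a year.
#' @return Discount factor in (0, 1].
#' @export
#' @examples
#' discount_factor(2, 0.03, 0.25) # 1.03^-0.25
discount_factor <- function(cycle_index, annual_rate = 0.03,
                            cycle_length_years = 0.25) {
  stopifnot(all(cycle_index >= 1), annual_rate >= 0)
  (1 + annual_rate)^(-(cycle_index - 1) * cycle_length_years)
}

#' Discounted quality-adjusted life years for one arm
#'
#' Utility-weighted time: for each cycle the post-transition occupancy is
#' weighted by the arm's band utilities and by the cycle length in years,
#' then discounted.
#'
#' @param trace A [run_trace()] result.
#' @param utilities A [utility_set()] (or a plain named 6-vector of means).
#' @param annual_rate,cycle_length_years Discounting settings.
#' @return Total discounted QALYs (scalar).
#' @export
accrue_qalys <- function(trace, utilities, annual_rate = 0.03,
                         cycle_length_years = 0.25) {
  stopifnot(inherits(trace, "cohort_trace"))
  u <- if (inherits(utilities, "utility_set")) utilities$mean else utilities
  u <- as.numeric(u)
  if (length(u) != 6L) stop("need one utility per band", call. = FALSE)
  k <- seq_len(trace$n_cycles)
  df <- discount_factor(k, annual_rate, cycle_length_years)
  occ <- trace$occupancy[k + 1L, , drop = FALSE]
  sum(df * cycle_length_years * as.numeric(occ %*% u))
}

#' Discounted total cost for one arm, itemized
#'
#' @param trace A [run_trace()] result.
#' @param costs A [cost_schedule()].
#' @param drug_active Whether this arm receives the drug.
#' @param strategy Strategy name, used to resolve a per-strategy
#'   administration cost.
#' @param annual_rate,cycle_length_years Discounting settings.
#' @return List with `total` (USD) and `items` (named breakdown: drug,
#'   administration, medication, diagnostics).
#' @export
accrue_costs <- function(trace, costs, drug_active, strategy = NULL,
                         annual_rate = 0.03, cycle_length_years = 0.25) {
  stopifnot(inherits(trace, "cohort_trace"), inherits(costs, "cost_schedule"))
  k <- seq_len(trace$n_cycles)
  df <- discount_factor(k, annual_rate, cycle_length_years)
  occ <- trace$occupancy[k + 1L, , drop = FALSE]

  admin <- costs$admin_cost_per_infusion
  if (length(admin) > 1L) {
    if (is.null(strategy) || is.na(match(strategy, names(admin)))) {
      stop("per-strategy admin cost needs a matching `strategy`", call. = FALSE)
    }
    admin <- admin[[strategy]]
  }

  drug <- if (drug_active) {
    sum(df * costs$drug_cost_per_dose * costs$doses_per_cycle)
  } else 0
  administration <- sum(df * admin)

  chronic <- mmd_bands()$is_chronic
  med <- costs$medication
  per_band <- ifelse(chronic,
                     med$mean[med$item == "cm_acute"] +
                       med$mean[med$item == "cm_prevention"],
                     med$mean[med$item == "em_acute"] +
                       med$mean[med$item == "em_prevention"])
  medication <- sum(df * as.numeric(occ %*% per_band))

  diagnostics <- sum(costs$diagnostics$unit_cost * costs$diagnostics$use_prob)

  items <- c(drug = drug, administration = administration,
             medication = medication, diagnostics = diagnostics)
  list(total = sum(items), items = items)
}

#' Incremental cost-effectiveness of two strategies
#'
#' Increments are intervention minus comparator on unrounded values; the
#' ICER is reported only when the incremental QALYs are non-zero, with
#' dominance flags otherwise ("dominant": cheaper and at least as
#' effective; "dominated": costlier and no more effective).
#'
#' @param cost,qalys Named length-2 numeric vectors (intervention first).
#' @return Object of class `ce_result`: per-strategy summary data.frame,
#'   `incremental_cost`, `incremental_qalys`, `icer` (NA unless defined),
#'   `status` one of "icer", "dominant", "dominated", "undefined".
#' @export
compute_icer <- function(cost, qalys) {
  if (length(cost) != 2L || length(qalys) != 2L) {
    stop("exactly two strategies are compared", call. = FALSE)
  }
  dc <- cost[[1L]] - cost[[2L]]
  de <- qalys[[1L]] - qalys[[2L]]
  if (dc == 0 && de == 0) {
    status <- "undefined"; icer <- NA_real_
  } else if (dc <= 0 && de >= 0) {
    status <- "dominant"; icer <- NA_real_
  } else if (dc >= 0 && de <= 0) {
    status <- "dominated"; icer <- NA_real_
  } else {
    status <- "icer"; icer <- dc / de
  }
  summary <- data.frame(
    strategy = if (!is.null(names(cost))) names(cost) else c("A", "B"),
    cost = as.numeric(cost), qalys = as.numeric(qalys),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, incremental_cost = dc,
                 incremental_qalys = de, icer = icer, status = status),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  cat(sprintf("incremental cost %.2f USD, incremental QALYs %.4f\n",
              x$incremental_cost, x$incremental_qalys))
  if (x$status == "icer") {
    cat(sprintf("ICER: %.0f USD/QALY\n", x$icer))
  } else {
    cat("status:", x$status, "\n")
  }
  invisible(x)
}

#' Net monetary benefit
#'
#' @param cost Total cost (USD).
#' @param qalys Total QALYs.
#' @param wtp Willingness-to-pay threshold (USD/QALY), >= 0.
#' @return `wtp * qalys - cost` (USD).
#' @export
net_monetary_benefit <- function(cost, qalys, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * qalys - cost
}
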