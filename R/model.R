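#' Build the decision model from a configuration
#'
#' Assembles validated strategy bundles (transition matrix, utilities, drug
#' flag), the shared cost schedule, the initial distribution and the
#' horizon/discount settings into a solvable model object.
#'
#' @param config A [load_config()] result; defaults to the shipped
#'   configuration reproducing the base case.
#' @return Object of class `cua_model`.
#' @export
build_model <- function(config = default_config()) {
  config <- validate_config(config)
  strategies <- lapply(names(config$strategies), function(s) {
    st <- config$strategies[[s]]
    m <- do.call(rbind, lapply(st$transitions$matrix, as.numeric))
    tm <- if (identical(st$transitions$orientation, "column")) {
      from_table1(m, strategy = s)
    } else {
      transition_matrix(m, strategy = s, normalize = TRUE)
    }
    list(name = s,
         tm = tm,
         utilities = utility_set(s, st$utilities$mean, st$utilities$sd),
         drug_active = isTRUE(st$drug_active))
  })
  names(strategies) <- names(config$strategies)

  medication <- do.call(rbind, lapply(config$costs$medication, as.data.frame))
  diagnostics <- do.call(rbind, lapply(config$costs$diagnostics, as.data.frame))
  costs <- cost_schedule(
    drug_cost_per_dose = config$costs$drug$per_dose,
    doses_per_cycle = config$costs$drug$doses_per_cycle,
    drug_uniform_halfwidth = config$costs$drug$uniform_halfwidth,
    admin_cost_per_infusion = config$costs$administration_per_infusion,
    medication = medication,
    diagnostics = diagnostics)

  idist <- config$initial_distribution
  profiles <- trial_profiles(vapply(config$trials, `[[`, numeric(1), "weight"))
  profiles$baseline_mmd_mean <-
    vapply(config$trials, `[[`, numeric(1), "baseline_mmd_mean")
  init <- switch(idist$method,
    explicit = stats::setNames(as.numeric(unlist(idist$weights)), band_labels()),
    analytic = initial_distribution(profiles, idist$beta_concentration,
                                    as.numeric(idist$support), "analytic"),
    sample = initial_distribution(profiles, idist$beta_concentration,
                                  as.numeric(idist$support), "sample",
                                  n = idist$n %||% 10000, seed = idist$seed))

  structure(list(
    strategies = strategies,
    costs = costs,
    init = init,
    profiles = profiles,
    n_cycles = config$model$cycles,
    cycle_length_years = config$model$cycle_length_years,
    discount_rate = config$model$discount_rate_annual,
    wtp_thresholds = as.numeric(config$model$wtp_thresholds),
    band_values = stats::setNames(as.numeric(config$bands$midpoints),
                                  band_labels()),
    config = config), class = "cua_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve the deterministic cohort model
#'
#' Runs the cohort trace for each strategy, accrues discounted costs and
#' QALYs, and computes the incremental comparison (first strategy vs
#' second).
#'
#' @param model A [build_model()] result.
#' @return List of class `cua_solution`: `traces`, `costs` (itemized),
#'   `qalys`, `mmd` (per-strategy [expected_mmd()] summaries), `ce`
#'   ([compute_icer()] result).
#' @export
solve_model <- function(model) {
  stopifnot(inherits(model, "cua_model"))
  traces <- lapply(model$strategies, function(st) {
    run_trace(model$init, st$tm, model$n_cycles)
  })
  qalys <- vapply(model$strategies, function(st) {
    accrue_qalys(traces[[st$name]], st$utilities,
                 model$discount_rate, model$cycle_length_years)
  }, numeric(1))
  costs <- lapply(model$strategies, function(st) {
    accrue_costs(traces[[st$name]], model$costs, st$drug_active,
                 strategy = st$name,
                 annual_rate = model$discount_rate,
                 cycle_length_years = model$cycle_length_years)
  })
  totals <- vapply(costs, `[[`, numeric(1), "total")
  mmd <- lapply(traces, expected_mmd, band_values = model$band_values)
  structure(list(traces = traces, costs = costs, total_cost = totals,
                 qalys = qalys, mmd = mmd,
                 ce = compute_icer(totals, qalys)),
            class = "cua_solution")
}

#' @export
print.cua_solution <- function(x, ...) {
  cat("Markov cohort cost-utility solution\n")
  for (s in names(x$qalys)) {
    cat(sprintf("  %-12s cost %8.2f USD  QALYs %.4f  MMD change %.2f\n",
                s, x$total_cost[[s]], x$qalys[[s]],
                x$mmd[[s]]$change_from_baseline))
  }
  print(x$ce)
  invisible(x)
}

#' Attach bootstrap transition uncertainty to a model
#'
#' Replaces each strategy's transition standard errors with those of a
#' [bootstrap_matrix()] estimate (means are kept at the model's values, by
#' default the published table).
#'
#' @param model A [build_model()] result.
#' @param estimates Named list of [bootstrap_matrix()] results, one per
#'   strategy.
#' @param replace_means Also replace the transition means with the
#'   bootstrap means (default `FALSE`).
#' @return The updated model.
#' @export
attach_transition_uncertainty <- function(model, estimates,
                                          replace_means = FALSE) {
  stopifnot(inherits(model, "cua_model"))
  for (s in names(model$strategies)) {
    if (is.null(estimates[[s]])) {
      stop("no bootstrap estimate for strategy ", s, call. = FALSE)
    }
    est <- estimates[[s]]
    p <- if (replace_means) est$mean else model$strategies[[s]]$tm$p
    model$strategies[[s]]$tm <-
      transition_matrix(p, strategy = s, se = est$se, normalize = TRUE)
  }
  model
}
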