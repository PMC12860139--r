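#' Default one-way sensitivity analysis specification
#'
#' One entry per varied parameter: every arm/band utility and every
#' informative transition probability varied by +/-10%, and every cost
#' parameter (drug acquisition, chronicity medication items,
#' administration, diagnostic bundle) by +/-20%.
#'
#' @param model A [build_model()] result.
#' @param utility_delta,transition_delta,cost_delta Relative half-ranges.
#' @return data.frame of parameter specifications for [run_owsa()].
#' @export
default_owsa_specs <- function(model, utility_delta = 0.10,
                               transition_delta = 0.10, cost_delta = 0.20) {
  stopifnot(utility_delta > 0, transition_delta > 0, cost_delta > 0)
  specs <- list()
  add <- function(id, type, low, high, arm = NA, band = NA,
                  from = NA, to = NA, item = NA) {
    specs[[length(specs) + 1L]] <<- data.frame(
      id = id, type = type, arm = arm, band = band, from = from, to = to,
      item = item, low = low, high = high, stringsAsFactors = FALSE)
  }
  for (s in names(model$strategies)) {
    for (b in band_labels()) {
      add(sprintf("utility %s, %s MMDs", s, b), "utility",
          1 - utility_delta, 1 + utility_delta, arm = s, band = b)
    }
  }
  for (s in names(model$strategies)) {
    p <- model$strategies[[s]]$tm$p
    informative_rows <- which(rowSums(p > 0) > 1L)
    for (i in informative_rows) {
      for (j in which(p[i, ] > 0)) {
        add(sprintf("transition %s, %s to %s", s,
                    band_labels()[i], band_labels()[j]),
            "transition", 1 - transition_delta, 1 + transition_delta,
            arm = s, from = band_labels()[i], to = band_labels()[j])
      }
    }
  }
  add("drug acquisition cost", "drug_cost", 1 - cost_delta, 1 + cost_delta)
  for (it in model$costs$medication$item) {
    add(paste("medication cost", it), "medication",
        1 - cost_delta, 1 + cost_delta, item = it)
  }
  add("administration cost", "admin", 1 - cost_delta, 1 + cost_delta)
  add("diagnostic work-up cost", "diagnostics", 1 - cost_delta, 1 + cost_delta)
  do.call(rbind, specs)
}

#' Apply a one-way parameter perturbation to a model
#'
#' @param model A [build_model()] result.
#' @param spec One row of an OWSA specification (see [default_owsa_specs()]).
#' @param multiplier Relative multiplier to apply.
#' @return The perturbed model. Utilities are clipped to (0, 1); perturbed
#'   transition rows are renormalized.
#' @export
perturb_model <- function(model, spec, multiplier) {
  type <- spec$type
  if (type == "utility") {
    st <- model$strategies[[spec$arm]]
    u <- st$utilities$mean
    u[spec$band] <- min(max(u[spec$band] * multiplier, 1e-6), 1 - 1e-6)
    model$strategies[[spec$arm]]$utilities <-
      utility_set(spec$arm, u, st$utilities$sd)
  } else if (type == "transition") {
    p <- model$strategies[[spec$arm]]$tm$p
    p[spec$from, spec$to] <- min(p[spec$from, spec$to] * multiplier, 1)
    rs <- sum(p[spec$from, ])
    if (rs <= 0) stop("perturbation empties transition row ", spec$from,
                      call. = FALSE)
    p[spec$from, ] <- p[spec$from, ] / rs
    model$strategies[[spec$arm]]$tm <-
      transition_matrix(p, strategy = spec$arm,
                        se = model$strategies[[spec$arm]]$tm$se)
  } else if (type == "drug_cost") {
    model$costs$drug_cost_per_dose <-
      model$costs$drug_cost_per_dose * multiplier
  } else if (type == "medication") {
    i <- match(spec$item, model$costs$medication$item)
    model$costs$medication$mean[i] <- model$costs$medication$mean[i] * multiplier
  } else if (type == "admin") {
    a <- model$costs$admin_cost_per_infusion
    if (!is.na(spec$arm) && !is.null(spec$arm)) {
      if (length(a) == 1L) {
        a <- stats::setNames(rep(a, length(model$strategies)),
                             names(model$strategies))
      }
      a[spec$arm] <- a[spec$arm] * multiplier
    } else {
      a <- a * multiplier
    }
    model$costs$admin_cost_per_infusion <- a
  } else if (type == "diagnostics") {
    model$costs$diagnostics$unit_cost <-
      model$costs$diagnostics$unit_cost * multiplier
  } else {
    stop("unknown OWSA parameter type: ", type, call. = FALSE)
  }
  model
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-solves the deterministic model with each parameter at its low and
#' high bound, all else held at base values.
#'
#' @param model A [build_model()] result.
#' @param specs OWSA specification data.frame; defaults to
#'   [default_owsa_specs()].
#' @return data.frame of class `tornado` sorted by bar width (descending):
#'   `parameter`, `icer_low`, `icer_high`, `status_low`, `status_high`,
#'   `width`, plus the base ICER as attribute `base_icer`. When a bound
#'   produces dominance the ICER is `NA` and the status column carries the
#'   flag.
#' @export
run_owsa <- function(model, specs = default_owsa_specs(model)) {
  base <- solve_model(model)
  if (base$ce$status != "icer") {
    stop("base case has no defined ICER (status: ", base$ce$status, ")",
         call. = FALSE)
  }
  one <- function(spec, mult) {
    ce <- solve_model(perturb_model(model, spec, mult))$ce
    list(icer = ce$icer, status = ce$status)
  }
  rows <- lapply(seq_len(nrow(specs)), function(r) {
    spec <- specs[r, ]
    lo <- one(spec, spec$low)
    hi <- one(spec, spec$high)
    data.frame(parameter = spec$id, type = spec$type,
               low = spec$low, high = spec$high,
               icer_low = lo$icer, icer_high = hi$icer,
               status_low = lo$status, status_high = hi$status,
               width = abs(hi$icer - lo$icer),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width, method = "radix", na.last = TRUE), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base$ce$icer
  class(out) <- c("tornado", "data.frame")
  out
}

# --- probabilistic sensitivity analysis ------------------------------------

# n sampled transition arrays (6 x 6 x n) for one strategy. Rows with
# standard errors get Dirichlet draws (concentration moment-matched to the
# largest-SE entry); rows without uncertainty stay fixed.
sample_transition_array <- function(tm, n) {
  arr <- array(rep(tm$p, n), dim = c(6L, 6L, n))
  if (is.null(tm$se) || all(tm$se == 0)) return(arr)
  for (i in seq_len(6L)) {
    if (all(tm$se[i, ] == 0) || sum(tm$p[i, ] > 0) < 2L) next
    nu <- dirichlet_concentration(tm$p[i, ], tm$se[i, ])
    arr[i, , ] <- t(rdirichlet_row(n, tm$p[i, ], nu))
  }
  arr
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n` independent joint parameter samples - Beta utilities (per arm
#' and band), Gamma medication and diagnostic costs (shared across arms),
#' Uniform drug acquisition cost, Dirichlet transition rows where standard
#' errors are attached (see [attach_transition_uncertainty()]) - and
#' re-solves the cohort model at each draw. With every standard deviation
#' zero and a degenerate Uniform the draws reproduce the base case exactly.
#'
#' @param model A [build_model()] result.
#' @param n Number of Monte Carlo draws (default 10000).
#' @param seed Seed; the same seed yields bit-identical results.
#' @return Object of class `psa_result`: `draws` (data.frame with
#'   per-strategy cost/QALYs and `dc`, `de`), `summary` (mean increments
#'   and probability cost-effective at the model's WTP thresholds), `n`,
#'   `seed`.
#' @export
run_psa <- function(model, n = 10000, seed = NULL) {
  stopifnot(inherits(model, "cua_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  arms <- names(model$strategies)
  L <- model$cycle_length_years
  k <- seq_len(model$n_cycles)
  df <- discount_factor(k, model$discount_rate, L)
  chronic <- mmd_bands()$is_chronic

  # --- joint parameter draws (fixed order for reproducibility) ---
  util <- lapply(arms, function(s) {
    us <- model$strategies[[s]]$utilities
    vapply(seq_len(6L), function(b) {
      rbeta_ms(n, us$mean[b], us$sd[b],
               paste0("utility ", s, " ", band_labels()[b]))
    }, numeric(n)) |> matrix(nrow = n)
  })
  names(util) <- arms
  med <- model$costs$medication
  med_draws <- vapply(seq_len(nrow(med)), function(i) {
    rgamma_ms(n, med$mean[i], med$sd[i], paste("medication", med$item[i]))
  }, numeric(n)) |> matrix(nrow = n, dimnames = list(NULL, med$item))
  dg <- model$costs$diagnostics
  diag_draws <- vapply(seq_len(nrow(dg)), function(i) {
    rgamma_ms(n, dg$unit_cost[i], dg$sd[i], paste("diagnostic", dg$item[i]))
  }, numeric(n)) |> matrix(nrow = n)
  diag_total <- as.numeric(diag_draws %*% dg$use_prob)
  hw <- model$costs$drug_uniform_halfwidth
  drug_mean <- model$costs$drug_cost_per_dose
  drug_draws <- if (hw > 0) {
    stats::runif(n, drug_mean * (1 - hw), drug_mean * (1 + hw))
  } else rep(drug_mean, n)
  trans <- lapply(arms, function(s) {
    sample_transition_array(model$strategies[[s]]$tm, n)
  })
  names(trans) <- arms

  admin <- model$costs$admin_cost_per_infusion
  admin_by_arm <- if (length(admin) > 1L) admin[arms] else
    stats::setNames(rep(admin, length(arms)), arms)

  per_band_med <- function(d) { # draw-specific chronicity cost vector
    ifelse(chronic, med_draws[d, "cm_acute"] + med_draws[d, "cm_prevention"],
           med_draws[d, "em_acute"] + med_draws[d, "em_prevention"])
  }

  cost <- matrix(NA_real_, n, length(arms), dimnames = list(NULL, arms))
  qaly <- cost
  init <- model$init
  for (d in seq_len(n)) {
    pb <- per_band_med(d)
    for (s in arms) {
      P <- trans[[s]][, , d]
      occ <- matrix(NA_real_, model$n_cycles, 6L)
      prev <- init
      for (kk in k) {
        prev <- as.numeric(prev %*% P)
        occ[kk, ] <- prev
      }
      qaly[d, s] <- sum(df * L * as.numeric(occ %*% util[[s]][d, ]))
      drug <- if (model$strategies[[s]]$drug_active) {
        sum(df * drug_draws[d] * model$costs$doses_per_cycle)
      } else 0
      cost[d, s] <- drug + sum(df * admin_by_arm[[s]]) +
        sum(df * as.numeric(occ %*% pb)) + diag_total[d]
    }
  }

  draws <- data.frame(draw = seq_len(n), cost, qaly, check.names = FALSE)
  names(draws) <- c("draw", paste0("cost_", arms), paste0("qaly_", arms))
  draws$dc <- cost[, 1L] - cost[, 2L]
  draws$de <- qaly[, 1L] - qaly[, 2L]

  prob_ce <- vapply(model$wtp_thresholds, function(wtp) {
    mean(wtp * draws$de - draws$dc > 0)
  }, numeric(1))
  summary <- list(mean_dc = mean(draws$dc), mean_de = mean(draws$de),
                  prob_cost_effective = stats::setNames(
                    prob_ce, paste0("wtp_", model$wtp_thresholds)))
  structure(list(draws = draws, summary = summary, n = n, seed = seed,
                 strategies = arms), class = "psa_result")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the probability that the
#' intervention is cost-effective is the fraction of draws with positive
#' incremental net monetary benefit (ties favour the comparator); the two
#' strategies' probabilities sum to 1 at every threshold.
#'
#' @param psa A [run_psa()] result (or a data.frame with `dc`, `de`).
#' @param thresholds Numeric grid of WTP thresholds (USD/QALY).
#' @return data.frame: `threshold`, `p_<intervention>`, `p_<comparator>`.
#' @export
ceac <- function(psa, thresholds = seq(0, 150000, by = 1000)) {
  if (!length(thresholds)) stop("empty threshold grid", call. = FALSE)
  draws <- if (inherits(psa, "psa_result")) psa$draws else psa
  arms <- if (inherits(psa, "psa_result")) psa$strategies else c("intervention", "comparator")
  p <- vapply(thresholds, function(wtp) {
    mean(wtp * draws$de - draws$dc > 0)
  }, numeric(1))
  out <- data.frame(threshold = thresholds, p1 = p, p2 = 1 - p)
  names(out) <- c("threshold", paste0("p_", arms))
  out
}
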