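# Shared fixtures, built in code.

# The published transition tables, re-typed here independently of the
# shipped YAML config (columns = from-state, rows = to-state, as printed).
printed_ept <- rbind(
  c(1.00, 0.56, 0.05, 0.01, 0.00, 0.00),
  c(0.00, 0.44, 0.74, 0.28, 0.04, 0.00),
  c(0.00, 0.00, 0.21, 0.61, 0.40, 0.08),
  c(0.00, 0.00, 0.00, 0.09, 0.53, 0.48),
  c(0.00, 0.00, 0.00, 0.00, 0.03, 0.36),
  c(0.00, 0.00, 0.00, 0.00, 0.00, 0.09))
printed_pla <- rbind(
  c(1.00, 0.29, 0.01, 0.00, 0.00, 0.00),
  c(0.00, 0.71, 0.53, 0.08, 0.00, 0.00),
  c(0.00, 0.00, 0.46, 0.61, 0.16, 0.01),
  c(0.00, 0.00, 0.00, 0.31, 0.64, 0.27),
  c(0.00, 0.00, 0.00, 0.00, 0.20, 0.50),
  c(0.00, 0.00, 0.00, 0.00, 0.00, 0.22))

base_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- build_model(default_config())
    m
  }
})

# a cost schedule with everything zeroed except what the caller sets
zero_costs <- function(drug = 0, admin = 0, cm_acute = 0, cm_prev = 0,
                       em_acute = 0, em_prev = 0, diag_cost = 0,
                       diag_prob = 0) {
  cost_schedule(
    drug_cost_per_dose = drug, doses_per_cycle = 1,
    drug_uniform_halfwidth = 0, admin_cost_per_infusion = admin,
    medication = data.frame(
      item = c("cm_acute", "cm_prevention", "em_acute", "em_prevention"),
      mean = c(cm_acute, cm_prev, em_acute, em_prev),
      sd = 0),
    diagnostics = data.frame(item = "x", unit_cost = diag_cost, sd = 0,
                             use_prob = diag_prob))
}

# model with all second-order uncertainty switched off (degenerate PSA)
degenerate_model <- function() {
  cfg <- default_config()
  for (s in names(cfg$strategies)) {
    cfg$strategies[[s]]$utilities$sd <- rep(0, 6)
  }
  cfg$costs$drug$uniform_halfwidth <- 0
  cfg$costs$medication <- lapply(cfg$costs$medication, function(x) {
    x$sd <- 0; x
  })
  cfg$costs$diagnostics <- lapply(cfg$costs$diagnostics, function(x) {
    x$sd <- 0; x
  })
  build_model(cfg)
}

# random row-stochastic 6x6 matrix
random_stochastic <- function() {
  p <- matrix(stats::rexp(36), 6, 6)
  p / rowSums(p)
}

# random point on the 6-simplex
random_simplex <- function() {
  w <- stats::rexp(6)
  w / sum(w)
}
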