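#!/usr/bin/env Rscript
# Step 5: probabilistic sensitivity analysis.
#
# 10,000 joint Monte Carlo draws: Beta utilities, Gamma medication and
# diagnostic costs (shared across arms), Uniform drug cost (+/-20%), and
# Dirichlet transition rows whose spread is moment-matched to the bootstrap
# SEs of step 2. Reports the cost-effectiveness plane summary, the
# probability cost-effective at the 1x and 3x GDP-per-capita thresholds,
# and the acceptability curve on a 0-150k USD/QALY grid.

suppressPackageStartupMessages(library(migrainecua))
seed <- 20260924 + 2

model <- build_model(default_config())
panel <- read_panel("results/synthetic_cohort.csv")
estimates <- lapply(names(model$strategies), function(s) {
  bootstrap_matrix(panel, s, n_resamples = 1000, seed = seed)
})
names(estimates) <- names(model$strategies)
model <- attach_transition_uncertainty(model, estimates)

psa <- run_psa(model, n = 10000, seed = seed + 1)
cc <- ceac(psa)

cat(sprintf("mean incremental cost %.0f USD, mean incremental QALYs %.4f\n",
            psa$summary$mean_dc, psa$summary$mean_de))
for (w in names(psa$summary$prob_cost_effective)) {
  cat(sprintf("  probability cost-effective at %s: %.1f%%\n",
              sub("wtp_", "WTP ", w),
              100 * psa$summary$prob_cost_effective[[w]]))
}
cross <- cc$threshold[min(which(cc$p_eptinezumab >= 0.5))]
cat(sprintf("  acceptability curve crosses 50%% near %d USD/QALY\n", cross))

write_outputs(list(psa = psa, ceac = cc,
                   metadata = list(seed = seed, n = psa$n)), "results")
cat("wrote results/psa_draws.csv and results/ceac.csv\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  wtp <- max(model$wtp_thresholds)
  d <- psa$draws
  d$ce <- wtp * d$de - d$dc > 0
  p1 <- ggplot(d, aes(de, dc, colour = ce)) +
    geom_point(alpha = 0.2, size = 0.5) +
    geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    scale_colour_manual(values = c("FALSE" = "firebrick", "TRUE" = "seagreen"),
                        guide = "none") +
    labs(x = "incremental QALYs", y = "incremental cost (USD)",
         title = sprintf("Cost-effectiveness plane (threshold %d USD/QALY)", wtp)) +
    theme_minimal(base_size = 10)
  ggsave("results/ce_plane.png", p1, width = 6, height = 5, dpi = 150)
  p2 <- ggplot(cc, aes(threshold)) +
    geom_line(aes(y = p_eptinezumab), colour = "steelblue") +
    geom_line(aes(y = p_placebo), colour = "firebrick") +
    labs(x = "willingness-to-pay (USD/QALY)", y = "P(cost-effective)",
         title = "Cost-effectiveness acceptability curves") +
    theme_minimal(base_size = 10)
  ggsave("results/ceac.png", p2, width = 6, height = 4, dpi = 150)
  cat("wrote results/ce_plane.png and results/ceac.png\n")
}
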