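---
title: "A six-state Markov cohort model for migraine prevention: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A six-state Markov cohort model for migraine prevention: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migrainecua)
```

## The model

The package evaluates quarterly intravenous anti-CGRP prophylaxis
(eptinezumab) against placebo for adults with migraine, from a
health-payer perspective, over a six-month horizon. Severity is the number
of monthly migraine days (MMDs), discretised into six bands: 0–3, 4–9 and
10–14 (episodic migraine) and 15–19, 20–24 and 24+ (chronic migraine,
defined as 15 or more MMDs). A cohort occupancy vector advances once per
12-week cycle by an arm-specific row-stochastic matrix; two cycles cover
the horizon. Mortality is excluded (the cohort's mean age is ~42 and the
horizon is six months), so occupancy is conserved, and treatment
discontinuation is ignored (trial discontinuation was below 1%). QALYs and
costs accrue each cycle on the *post-transition* occupancy — treatment is
given at the start of each cycle and the transition realises its effect —
and are discounted at 3% per year with the first cycle undiscounted. With
a six-month horizon the discounting convention moves results by well under
1%.

Band labels deserve one note: the published state labels overlap ("20–24"
and "24+"). States must partition the integers, so internally the fifth
band is 20–23 and the sixth 24 and above, while the display labels keep
the published form. Fractional MMD values are rounded half-up before
banding, because bands are defined on whole days.

## Inputs and where each number comes from

All inputs live in one YAML configuration
(`inst/extdata/default_config.yaml`, loaded by `default_config()`); every
entry below is overridable there.

**Transition matrices.** The published tables are column-oriented (columns
are from-states) and carry rounding error: one column sums to 0.99 and one
to 1.01. `from_table1()` transposes to row-stochastic form and renormalizes
each row to sum exactly to 1; a column summing outside [0.95, 1.05] is
rejected as mis-keyed. After renormalization no entry moves by more than
0.01, the table's stated rounding slack.

**Initial distribution.** Not published directly. The cohort enters with
baseline MMDs drawn from an equal-weight mixture of three trial profiles
with baseline means 10.0, 20.4 and 14.5 MMDs (trial sizes are not model
inputs, hence equal weights). Each component is a Beta distribution scaled
to [4, 28] — trial entry required at least four MMDs — with its mean fixed
at the trial mean and total concentration 10, a spread that keeps each
trial's mass across two to three adjacent bands rather than degenerate at
one. The default derivation integrates this mixture over the band cut
points (`initial_distribution(method = "analytic")`), which is exactly the
large-sample limit of banding a sampled cohort and keeps the base case
deterministic; `method = "sample"` reproduces it stochastically. The
result puts roughly half the cohort in chronic states at baseline
(expected baseline ≈ 14.9 MMDs by band midpoints).

**Utilities.** Band- and arm-specific means and SDs on the EQ-5D scale
(0.778 down to 0.553 treated; 0.707 down to 0.483 placebo), strictly
decreasing in severity; `utility_set()` validates that each (mean, SD)
pair admits a Beta by method of moments.

**Costs (2024 USD).** Drug acquisition $1,708 per dose, one dose per
cycle, treated arm only. Acute plus preventive medication costs accrue per
cycle by the chronicity of the current band (chronic: 270.0 + 37.0;
episodic: 184.0 + 27.4). A published alternative — one non-state-specific
acute/preventive pair — is retained in the configuration as a scenario but
excluded from the base case to avoid double counting. Diagnostic and
procedure unit costs (MRI 195.9, CT 114.5, ECG 4.5, skull X-ray 6.0, blood
test 6.0, botulinum toxin 110.4, TENS 9.6, occipital nerve block 0.7) form
a one-time expected work-up at entry, `Σ unit cost × use probability`.

**Calibrated entries.** Two inputs are not published: the per-item
diagnostic use probabilities and the administration fee (the placebo arm
incurs "administrative costs only", magnitude unstated). They were set
once — use probabilities (0.50, 0.25, 0.70, 0.25, 0.90, 0.50, 0.50, 0.70)
and $203 per infusion visit for both arms — so that the placebo arm's
six-month total lands at its published value (~$1,065), and never
revisited. Both are flagged as calibrated in the configuration. Because
they are identical in both arms they cancel out of the incremental
comparison, which the tornado analysis makes visible as zero-width bars.

## Transition estimation

Patient-level trial data are not deposited, so `generate_cohort()` is a
first-class synthetic stand-in: patients draw a trial by weight, a
baseline MMD from that trial's scaled Beta, sex (78% female) and age
(trial means 40.0–44.6, SD 11 — a typical trial-population spread, as no
SD is published) independently of MMD, and a 1:1 randomized arm; each
cycle the band advances by the arm's transition row and a concrete MMD is
drawn uniformly within the new band (the open top band uses [24, 30]).
Age and sex are carried for cohort realism but do not enter the economic
model.

`bootstrap_matrix()` estimates a single stationary matrix per arm:
baseline→cycle-1 and cycle-1→cycle-2 band pairs are pooled (the model uses
one matrix per arm), patients — not individual transitions — are resampled
with replacement to preserve within-patient correlation, each resample is
row-normalized with a never-departed band falling back to self-transition
1 (keeping matrices stochastic; the published zeros show the trials'
structural sparsity), and the elementwise standard deviation across 1,000
resamples is the standard error. At 1,000 patients the bootstrap means
recover the generating matrices within two SEs in ≥ 95% of informative
entries — the round-trip property the test suite asserts.

What the generator does *not* emulate: treatment discontinuation and
missing visits, serial correlation beyond the first-order Markov
structure, any within-band MMD distribution other than uniform, and
covariate effects on transitions. Passing round-trip tests therefore show
estimator correctness under the model's own assumptions, not that real
trajectories are Markovian.

## Sensitivity analyses

**One-way (tornado).** Every arm/band utility and every informative
transition probability varies by ±10%, every cost parameter by ±20%, one
at a time; the model is re-solved at each bound (utilities clipped to
(0, 1); a perturbed transition row renormalized). Bars are sorted by
|ICER(high) − ICER(low)|. If a bound produces dominance the ICER is
reported as an explicit `NA` with a status flag, never a fabricated
number.

**Probabilistic.** Each of 10,000 draws samples utilities (Beta, per arm
and band), medication and diagnostic costs (Gamma, shared by both arms —
unit costs are common national prices), drug cost (Uniform, ±20% around
$1,708: the only published cost-variation magnitude, adopted as the
distribution's bounds), and transition rows. Rows use a Dirichlet per
from-band — the natural simplex-preserving choice; independent Betas would
need ad-hoc renormalization — with total concentration moment-matched to
the row's largest-SE entry, SEs coming from the bootstrap on the synthetic
cohort (they are not published). Parameters are drawn independently; any
real correlation (e.g. between arms' utilities) is a documented
limitation, and shared cost draws already remove the spurious
between-arm cost noise. All draws come from one sequential RNG stream
under a single seed, so results are bit-reproducible; there is no
parallelism to complicate that guarantee. With every SD zero and a
degenerate Uniform, each draw reproduces the base case exactly — the
regression test that guards the PSA's plumbing.

The acceptability curve evaluates `P(λΔE − ΔC > 0)` on a λ grid of 0 to
150,000 in steps of 1,000 USD/QALY, covering both decision thresholds;
ties favour the comparator, and the two arms' probabilities sum to 1 at
every threshold by construction.

## Numerical choices and degenerate inputs

Row-stochasticity is enforced to 1e-9; occupancy conservation likewise.
ICERs are computed on unrounded increments, with explicit dominance flags
on the four (sign ΔC, sign ΔE) quadrants and an undefined flag at
ΔE = ΔC = 0 rather than an exception. Method-of-moments conversions
reject infeasible inputs by name (a Beta SD too large for its mean, a
Dirichlet SE too large for its probability). Representative band values
for MMD summaries are the midpoints (1.5, 6.5, 12, 17, 21.5) with 26 for
the open band — no mapping is published; values outside their band warn.

Problem sizes are chosen to keep every stage interactive: the
deterministic solve is microseconds; the full pipeline (1,000-patient
cohort, 1,000 bootstrap resamples per arm, 10,000 PSA draws) runs in a
couple of seconds on one CPU.

## Open design questions, resolved

The study software's description leaves ambiguous whether the base case
was a patient-level microsimulation or a cohort model with parameter-level
Monte Carlo. This package implements the deterministic cohort base case
with a parameter PSA: the cohort trace is the exact expectation of the
microsimulation under the same matrices, so the base-case means agree
while remaining seed-free; only patient-level spread (e.g. the SDs quoted
alongside MMD reductions) requires microsimulation, and the synthetic
cohort module provides that route where needed. Medication costs are
treated as per-cycle accruals resolved by the current band —
state-dependent accrual is the point of a Markov structure, and it places
the placebo total at its published value.

## Known limitations

* **Compounding MMD reductions.** A stationary per-cycle matrix applied
  for two cycles drives the expected MMD down at both steps (treated:
  14.9 → 9.7 → 6.0; placebo: 14.9 → 11.6 → 8.9 by band midpoints), giving
  six-month reductions of ~8.9 and ~6.0 days. Observed trial trajectories
  plateau after the first dosing interval, and the published six-month
  reductions (5.8 and 3.8 days) match this model's *first-cycle* change
  (~5.2 and ~3.3 days) far better than its two-cycle change. The
  between-arm difference is less affected (~2.9 vs ~1.9 days). Costs,
  QALYs and the ICER are driven by occupancy, not by the MMD summary, and
  are reproduced within a few percent; but the final-cycle MMD reduction
  should be read as a model artefact of stationarity, and
  `expected_mmd()` therefore exposes the full per-cycle trajectory rather
  than only the endpoint.
* Utilities transfer from a different anti-CGRP antibody studied in
  East-Asian populations; no local, drug-specific quality-of-life data
  exist yet, and the tornado shows the 4–9-MMD utility is the single most
  influential parameter.
* The two calibrated entry-cost inputs are identifiable only as a bundle;
  any split between administration fee and diagnostic probabilities with
  the same total is observationally equivalent in this model.
* Six-month horizon, no discontinuation, no societal costs, no mortality:
  structural exclusions inherited from the study design, not estimable
  from the shipped inputs.
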