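---
title: "Latent brain-state dynamics: model, metrics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent brain-state dynamics: model, metrics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainstates)
```

## The scientific problem

Static functional connectivity averages a resting-state scan into one
number per region pair. `brainstates` instead treats the scan as a sequence
of recurring whole-brain activation patterns and asks *how the brain moves
between them*: how long it dwells in a pattern, how often it switches, and
whether those dynamics differ between groups — here a sex × diagnosis
(ADHD vs. typically developing) factorial design over children scanned at
multiple sites.

## Model and assumptions

Each scan is a `T × C` matrix of parcel time courses (`C` ≈ 190 regions for
a standard functional parcellation). The generative model per group is a
Gaussian-emission hidden Markov model:

- a latent state sequence follows a first-order, time-homogeneous Markov
  chain (initial distribution π, transition matrix A);
- conditional on the state, observations are Gaussian with state-specific
  mean map μ_k and (by default) diagonal covariance;
- states are mutually exclusive: the brain is in exactly one state per TR.

Assumptions worth keeping in mind: first-order memory (no duration
modelling — dwell times are implicitly geometric), emission stationarity
within a group, and independence of runs (the chain restarts at every scan
boundary; no transition probability is spent across runs, because a
transition between two different children is physically meaningless).

Estimation is maximum-likelihood EM (Baum–Welch). The reference analysis
this design follows described its estimator as Bayesian but reported no
priors and compared models by log probability; ML-EM reproduces that
workflow exactly, so we implement ML-EM only and document the equivalence
here rather than offering a token MAP switch.

## Tunable parameters that matter

| parameter | default | why |
|---|---|---|
| `K` (states) | scan 1..10, elbow; 5 in the reference design | maximum second difference of log-likelihood; ties to smaller K; full Δ/Δ² table returned for manual override |
| covariance | diagonal | with C ≈ 190 channels a full C × C per state is data-hungry; `full` available |
| EM restarts | 5 | k-means initializations differ per restart; best final log-likelihood wins. Fewer restarts demonstrably find merged-state local optima on 5-state cohorts |
| `tol` | 1e-4 relative | log-likelihood plateau criterion; `max_iter` 200 |
| variance floor | 1e-6 | prevents emission collapse onto single observations |
| alignment `n_init` | 50 | k-means on only 4K ≈ 20 points; global optimum near-certain |
| ITI convention | `dwell_minus_one` | see below |
| outlier threshold | 3 SD, pooled, single pass, strict inequality | values at exactly |z| = 3 are retained |
| ANOVA SS | Type III, sum-to-zero contrasts | psychology convention for unbalanced factorial designs; Type II by flag |

## The ITI convention

The verbal definition of the inter-transition interval — consecutive time
points in a state before a switch — reads as the dwell length L. But the
reference design's own numbers are only mutually consistent with L − 1: an
on-diagonal transition probability of 0.53 implies geometric mean dwell
1/(1 − 0.53) ≈ 2.13 TRs and a switching rate near 0.47, while the reported
mean ITI is ≈ 1.1–1.17 ≈ 2.13 − 1. We therefore default to
`dwell_minus_one` ("extra" time points spent in a state beyond its first)
and implement `dwell` as an option. The final, right-censored episode of
each run is included: no truncation rule is stated anywhere, and short runs
would otherwise lose a large fraction of their episodes.

Exact identities used as tests: per run, episodes = transitions + 1, so
mean dwell = T/(transitions + 1) and
|mean dwell − 1/NT| = T/(transitions · (transitions + 1)) exactly.

## The synthetic cohort: what it emulates, what it does not

`gt_config()` defaults state a world shaped like the reference cohort:

- four groups with scan counts 99/347/251/257 (954 runs; scans, not
  subjects, are the analysis units — the reported error degrees of freedom
  are only consistent with run-level units);
- run lengths uniform on 80–230 TRs (multi-site duration heterogeneity);
- 190 channels; five states; group-mean on-diagonal transition probability
  0.53 with the remaining mass spread evenly (off-diagonal ≈ 0.118);
- an injected sex effect on dwell dynamics — girls' on-diagonal 0.50,
  boys' 0.56 — and an injected diagnosis effect on switching
  *variability*: each run's transition matrix is a row-renormalized
  logit-space perturbation of its group's matrix, with SD 1.0 for ADHD
  runs versus 0.5 for controls.

The jitter SDs were calibrated once, before any acceptance measurement, by
a standalone dwell-time simulation: 0.5/1.0 puts the recovered boy − girl
ITI effect at Cohen's d ≈ 0.3 at the full cohort size, the scale of the
reference design's per-state effects (≈ 0.2–0.35). They were not revisited.

State templates default to a deterministic block pattern with amplitude
2 × the emission noise SD, i.e. a 2-SD mean separation between any two
states on their signature channels. Emission noise is iid Gaussian.

Not emulated: hemodynamic autocorrelation, spatial smoothness across
parcels, scanner drift, site batch effects beyond run length, motion, and
subject-level repeated scans (the generator emits one scan per synthetic
subject, though the ingest layer fully supports multi-scan subjects).
A green recovery test therefore establishes that the estimator and metric
chain are correct *under the model's own assumptions* — not that the model
is adequate for any particular real dataset.

## State alignment

Groups are fitted independently, so state labels are arbitrary per group.
Alignment runs Euclidean k-means on the stacked 4K mean activation maps
(raw vectors — no correlation distance, no re-standardization; the simplest
reading of clustering "on the mean activation maps"), with validity defined
as every cluster containing exactly one map per group. Consensus maps are
arithmetic means of the four members; consensus labels are ordered by
descending total absolute activation — an imposed, documented convention,
since state numbering carries no meaning. Shared-template worlds validate
in ≥ 9/10 seeds; template-free worlds (independent random maps per group)
essentially never do, and both behaviours are asserted in tests.

## Inference layer

`two_way_anova()` computes Type III sums of squares by column-dropping on a
sum-contrast model matrix (cross-checked against an independent
general-purpose implementation to 1e-6 relative in F). Partial η² is
SS_effect/(SS_effect + SS_error), invariant to affine metric rescaling.

`mixed_anova_fo()` is a split-plot design: sex and diagnosis between runs,
state within (the run is the repeated-measures unit), Type III in each
stratum, within-stratum error df (K − 1)(N − 4). Because each run's FO
vector sums to one, the between-run stratum is degenerate for FO (all run
means equal 1/K) — the scientifically meaningful rows are the within-run
ones, in particular sex × diagnosis × state. The built-in simplex
collinearity is handled by construction (run-centering annihilates
run-constant columns exactly). The reference analysis's exact error-df
bookkeeping cannot be reconstructed from what is reported; this design is
declared, not claimed identical.

Per-state tests use pooled-variance t-tests and pooled-SD Cohen's d (sign:
second group minus first), with no multiple-testing correction by default
(raw p values are what the reference reports; Holm available). Outlier
screening is applied separately per metric family (ITI-based vs NT),
mirroring the separate removals in the reference workflow. The ITI–NT
correlation is computed on screened records; on raw records the calibrated
cohort's heavy between-run tail attenuates it (≈ −0.85 raw vs ≈ −0.94
screened).

## Numerical choices

- Forward–backward uses per-step scaling (C++); posteriors renormalized per
  row; log-likelihood accumulated with per-row max-shifts.
- Viterbi runs in log space; ties break toward the lower state index,
  deterministically (a fully symmetric model decodes to all-state-1).
- Empty EM states (posterior mass < 1e-8) are re-seeded at the observation
  with the lowest total density and the event is logged in the fit object.
- Rows of an empirical TPM with no outgoing transitions are reported as NA
  ("undefined"), never as silent zeros.
- All randomness flows from one integer seed through `derive_seed()`
  (a deterministic hash of stage/group/restart labels), so pipeline re-runs
  are byte-identical and no seed bookkeeping is needed.

## Acceptance-scale choices

Criteria that leave simulation sizes open are scaled for a single CPU:
elbow selection uses 10 cohorts of 25 runs × 120 TRs × 20 channels
(scan K = 1..10), alignment validity uses 10 cohorts of 4 × 10 runs, and
the effect-direction check uses 20 replicates of 4 × 50 runs × 120 TRs ×
30 channels. Recovery fits use the default 5 restarts; with 2, one seed in
five found a merged-state optimum — that observation is why the default is
what it is.

## Known limitations

- Geometric dwell times only; no explicit duration modelling.
- Diagonal emission covariance by default; states are defined by mean
  activation, not by covariance structure.
- Elbow selection is a heuristic; the Δ² table is returned precisely so a
  human can overrule it.
- FO comparisons across groups inherit any residual mismatch in the
  aligned maps; group differences in FO should be read with that caveat.
- Dwell metrics are reported in TR units, not seconds: repetition time
  varies across sites, and converting would suggest a precision the data
  do not have.
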