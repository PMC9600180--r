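---
title: "Methods: rare-taxon dynamics and stability-landscape recovery modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-taxon dynamics and stability-landscape recovery modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators and design choices behind
`rarestab`, in the spirit of a methods supplement: what each stage assumes,
which knobs matter, and what the synthetic-data tests do and do not
establish about real communities.

## The scientific setting

Soil mesocosms from two fertilization histories (chemical, NCF; organic,
NOF) are exposed to pulse disturbances — drought (DR), flooding (FL),
freeze–thaw (FR), heat (HE) and an ambient control (AMB) — and sampled
before disturbance (initial) and at four recovery times (R0, R2, R40,
R170 days). OTU count tables over these samples are the raw material. The
analysis asks three linked questions: which abundance classes of taxa
carry the community's response, how far each subcommunity is displaced
from its initial state, and whether diversity relaxes back to the old
equilibrium or settles at a new one.

## Taxon classification

Classification happens once per soil, from that soil's initial samples
only, at two relative-abundance cutoffs: `rare_cutoff` = 1e-4 (0.01%) and
`abundant_cutoff` = 1e-2 (1%). The six predicates (AAT, CAT, MT, CRT, ART,
CRAT) partition every OTU; OTUs absent from all initial samples are NEW
and counted as rare. Boundary convention: a proportion exactly at 0.01%
is moderate-side (rarity requires strictly `< 0.01%`), a proportion
exactly at 1% is abundant-side (`>= 1%`). An OTU observed in some initial
replicates but zero in others participates with those zeros as rare-side
observations — it is not NEW; NEW requires absence from *all* initial
samples of the soil.

Two consequences are worth knowing. First, classification depends on the
sequencing depth through the detection limit: at depth 10,000 one read is
already 0.01%, so ART (positive but `< 0.01%` everywhere) cannot occur and
all rare OTUs are CRT; at the study-scale depth of 67,899 the rare
boundary sits near seven reads and ART dominates. Second, CRAT OTUs (rare
in some initial samples, `>= 1%` in others) are possible in principle;
when they occur they are grouped with rare taxa by default
(`crat_group = "rare"`, configurable) — the abundant/common/rare grouping
used everywhere downstream is abundant = AAT+CAT, common = MT,
rare = ART+CRT+NEW.

## Diversity and log response ratios

Rarefaction draws each sample's reads without replacement (sequential
conditional hypergeometric), seeded and depth-conserving. Shannon
diversity is computed on taxon-group subcommunities after renormalizing
within the subset (equivalent to computing on the subset counts); a sample
in which the group has no reads yields `NA`, never 0. Natural logarithms
are used throughout, for Shannon and for the log response ratio
LRR = ln(H_sample / H_initial). "Pairwise" LRR crosses every
post-disturbance sample with each same-soil initial replicate
(`pairing = "all_pairs"`); a replicate-mean variant is available because
the aggregation level is a genuine design freedom — all-pairs is the
default as it keeps the initial replicates' spread visible.

## Community structure

Bray–Curtis, PCoA, PERMANOVA and SIMPER are implemented from their
definitions rather than wrapped, and are cross-checked against vegan in
the test suite. Choices that were genuinely open:

- *Dissimilarity to initial* is the mean of pairwise Bray–Curtis distances
  to the same-soil initial replicates (self-pairs excluded for initial
  samples), not the distance to a centroid profile — consistent with
  SIMPER's pairwise logic.
- *PERMANOVA* uses sequential (Type-I) sums of squares with term order
  (disturbance, time), free permutation of sample labels, and
  p = (1 + #{F* ≥ F}) / (1 + n_perm) with 999 permutations by default. At
  small n the p-value is discrete and slightly conservative because label
  permutations within the same group partition tie the observed statistic.
- *PCoA* retains negative eigenvalues in the output but excludes those
  axes from coordinates; a Lingoes correction is available behind a flag.
  Variance proportions are reported relative to the sum of positive
  eigenvalues.
- *Taxon-group community matrices* subset the OTUs of a group and
  renormalize within the group, mirroring the subcommunity Shannon
  convention.

## Responsive-OTU detection

The differential-abundance stage is a deliberately compact
negative-binomial Wald pipeline, not a wrapper around a full-featured DA
package: median-of-ratios size factors; per-OTU method-of-moments
dispersions (variance = μ + αμ²) pooled within groups; a parametric
mean–dispersion trend α(μ) = a₀ + a₁/μ; and log-normal empirical-Bayes
shrinkage of each dispersion toward the trend. The shrinkage weight
compares the delta-method sampling variance of a log-dispersion moment
estimate against the robust (MAD-based) spread of log residuals around
the trend, with floored estimates excluded from the spread — they carry
censoring artifact, not information. Wald tests fit a log-link NB GLM per
OTU by IRLS with the dispersion plugged in; the shrunken log2 fold change
refits under a zero-centered normal prior on the group coefficient
(`lfc_prior_sd` = 2 on the natural-log scale — weak enough to leave
well-measured effects almost untouched, strong enough to pull noise-driven
extreme LFCs in). The responsive filter keeps q < 0.05 and
|log2FC| > 1, on the shrunken LFC by default since shrinkage precedes
filtering in the procedure this reimplements. Independent filtering and
outlier replacement are intentionally omitted. Groups with all-zero
counts make the Wald machinery degenerate; such OTUs are flagged
(`zero_group`) with p = 1 rather than silently called.

Simulation suites calibrate this stage: empirical type-I error at nominal
0.05 over 2,500 null NB OTUs (α = 0.2, 4+4 replicates, ~10 reads per
sample) must sit inside the 95% binomial interval, and power for 4-fold
changes planted in both directions (20% of the community responsive, the
strong-disturbance regime) must exceed 0.8 at q < 0.05.

## The stability-landscape model

Recovery is modelled as the impulse response of a damped system in a
stability landscape:

x(t) = D·t·e^(φ₁t) + A·(1 − e^(−φ₂t))

with x the Shannon displacement from the pre-disturbance baseline, D > 0
the perturbation strength, A the new-equilibrium displacement (asymptote),
φ₁ (per model-time unit, negative for decay) the impulse decay rate and φ₂
the approach rate to the new equilibrium. x(0) = 0 by construction and
x(t) → A when φ₁ < 0, φ₂ > 0. This critically-damped form (the damping and
restoring-force strength of the underlying second-order system are
b = −2φ₁, k = φ₁², reported for reference) was fixed as the canonical
parameterization because it has the right boundary behavior and is
sign-consistent with reported fits (φ₁ medians negative, φ₂ mostly
positive); an overdamped two-exponential alternative is available via
`form = "overdamped"`. Model time maps timepoints to ordinals (initial = 0,
R0 = 1, ..., R170 = 4) by default; a calendar-day mapping can be supplied.
The response variable is each sample's Shannon displacement from the mean
initial Shannon of the same soil × taxon group — a fixed baseline, not an
estimated parameter — and replicates enter as individual points rather
than means.

The Bayesian fit uses uniform box priors D ∈ (0, 10), A ∈ (−2, 2),
φ₁ ∈ (−2, 2), φ₂ ∈ (−2, 2) (wide enough that reported credible intervals
for such experiments sit inside) and a half-normal(1) prior on the
Gaussian noise sd σ, floored at 1e-4 so degenerate (noise-free) data
cannot drive the likelihood singular. Sampling is by an affine-invariant
stretch-move ensemble (32 walkers, a = 2), which self-tunes to the
strongly correlated D–φ₁ ridge this likelihood has. Walkers start in a
1e-3-radius Gaussian ball around a posterior mode found by 8-start
L-BFGS-B, a standard ensemble-sampler initialization. Defaults are 5,000
steps with 1,000 burn-in; convergence is monitored by split-chain R-hat
per parameter (flagged above 1.05) and a Geyer-style effective sample
size. The split-R-hat over walker chains is conservative for ensembles —
walkers are cross-correlated — so a flag slightly above threshold warrants
longer chains rather than distrust of the medians; for headline fits the
analysis uses 20,000–50,000 steps, where medians are stable to well under
a percent.

Two properties of the posterior matter when interpreting medians. The
D–φ₁ ridge (a larger impulse decaying faster fits almost equally well)
makes D's marginal right-skewed, so D's posterior median sits a few
percent above the generating value in recovery simulations even at
moderate noise; A and φ₁ recover within ~1–2%. And the skewness of A's
marginal is itself the diagnostic used to distinguish "leaning back toward
the old equilibrium" (sign toward zero) from "leaning further away".

## The synthetic-community generator

The generator produces data with the statistical structure the analysis
assumes, so the whole pipeline is testable without sequencing runs:

- True OTU proportions per soil are drawn once from a lognormal
  species-abundance distribution (σ = 2.5 on the log scale, pool of
  20,000 OTUs by default) and shared across that soil's initial
  replicates; reads are multinomial at fixed depth (10,000 by default for
  speed, 67,899 to mirror the study scale). The defaults were calibrated
  once against the reported initial-community partitioning — ~0.1–0.2% of
  observed OTUs abundant carrying ~20–30% of reads, ~90% rare carrying
  ~20% — and then frozen.
- Disturbance scenarios act as taxon-group log-fold multipliers on the
  true proportions, with per-OTU lognormal jitter (sd 0.3) so OTU-level
  tests face heterogeneous effect sizes. Crucially, the group each OTU
  belongs to is determined by classifying the *observed* initial samples —
  the same operation the analysis performs — so OTUs below the detection
  limit count as rare and can bloom into newly detected taxa, and
  generator effects land on the groups the analysis will interrogate.
- Invading OTUs (ids disjoint from the initial pool) enter with a
  Dirichlet split of a configured mass: 10% of reads for flooding, 20%
  for heat, persisting through recovery — strong disturbances shift the
  community to a new equilibrium assembled around rare taxa. Drought and
  freeze–thaw are weaker, invader-free, and decay over the recovery
  period (time profile 1, 0.8, 0.5, 0.2), emulating relaxation back
  toward the initial state. Ambient is an exact null (zero effects, no
  invaders) and doubles as the calibration control. Scenario effects can
  alternatively be modulated by an impulse-response curve via
  `trajectory_params`.
- Diversity trajectories for the model-fitting tests are simulated
  directly from the analytic curve plus iid Gaussian noise.

What the generator does *not* emulate: phylogenetic or taxonomic
structure, OTU–OTU correlations (draws are multinomial given the
perturbed proportions), overdispersion beyond multinomial sampling in the
counts, depth variation across samples (data are treated as
post-rarefaction), and chimeras/sequencing error (the upstream
bioinformatics is out of scope). Passing tests therefore establish the
*internal consistency* of the pipeline — estimators recover what the
generator planted, directions match the documented findings — not that
real soils behave this way.

## Problem sizes and numerical conventions

The test suite runs at deliberately desk-friendly sizes: toy tables of
tens of OTUs for oracle comparisons, 2,500-OTU simulations for test
calibration, a 20,000-OTU end-to-end scenario, and recovery fits on
25 time points × 4 replicates with noise sd 0.05 — the configuration also
used by `scripts/acceptance.R`. Classification agreement is exact against
a brute-force predicate enumerator; SIMPER conservation is enforced to
1e-9; BH agreement with the step-up reference is exact; PERMANOVA p-values
are compared with exhaustive enumeration on ≤8-sample instances. Ties in
permutation tests count toward the extreme tail (F* ≥ F − 1e-12). All
randomness flows from explicit integer seeds; re-running any stage with
the same configuration reproduces its outputs bit-identically.

## Known limitations

- The NB Wald test is asymptotic; at 4+4 replicates its calibration
  depends on the dispersion shrinkage doing its job, and its FDR control
  degrades when effects are extremely abundant and one-directional
  (size factors then absorb part of the signal — a compositional limit,
  not a bug).
- The impulse-response form is one of several plausible recovery shapes;
  no model selection across landscape shapes is attempted, and fits with
  φ₂ < 0 (divergent relaxation) are mathematically admitted by the prior
  box but not physically interpretable as recovery.
- Posterior medians inherit the D-ridge skew discussed above; report
  credible intervals, not medians alone.
- LRR requires positive Shannon values on both sides of a pair; groups
  collapsing to a single OTU (H = 0) drop out with a warning.
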