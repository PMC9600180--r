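# rarestab

Temporal dynamics and stability of rare and abundant soil bacterial taxa
under environmental disturbance.

`rarestab` is an R package plus analysis workflow for disturbance–recovery
mesocosm experiments on soil microbiomes. It targets the common design in
which soils from different management histories (here: long-term chemical,
NCF, vs organic, NOF, fertilization) are exposed to pulse disturbances —
drought (DR), flooding (FL), freeze–thaw cycles (FR), heat (HE), plus an
ambient control (AMB) — and 16S OTU communities are profiled before the
disturbance (initial) and at several recovery times (R0, R2, R40, R170
days). The package answers, with tested code: which abundance classes of
taxa absorb the disturbance, how far the community is displaced, and
whether it relaxes back to its original equilibrium or settles in a new
one.

## What it implements

- **Rare-biosphere classification.** Every OTU is classified from the
  initial samples of one soil at the 0.01% / 1% relative-abundance cutoffs:
  always abundant (AAT, ≥ 1% in all initial samples), conditionally
  abundant (CAT), moderate (MT), conditionally rare (CRT), always rare
  (ART), conditionally rare-and-abundant (CRAT), with OTUs absent from all
  initial samples labelled NEW and grouped with rare taxa. Group shares and
  Sankey-style flows track the abundant/common/rare partition over time.
- **Diversity.** Seeded rarefaction (multivariate hypergeometric), Shannon
  index H = −Σ pᵢ ln pᵢ per taxon-group subcommunity, and pairwise log
  response ratios LRR = ln(H_sample / H_initial).
- **Community structure, from definitions.** Bray–Curtis dissimilarity
  BC(x, y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ), principal-coordinate analysis, PERMANOVA
  with sequential sums of squares and permutation p-values, SIMPER
  decomposition of between-group dissimilarity into per-OTU and
  per-taxon-group contributions, and per-sample dissimilarity to the
  initial community.
- **Responsive OTUs.** A compact negative-binomial Wald pipeline:
  median-of-ratios size factors, method-of-moments dispersions shrunk
  toward a mean–dispersion trend, per-OTU NB GLM Wald tests of each
  recovery timepoint against initial, ridge-shrunken log2 fold changes,
  Benjamini–Hochberg correction, and the q < 0.05, |log2FC| > 1 responsive
  filter.
- **Stability-landscape model.** Community recovery is modelled as the
  impulse response of a damped system,

      x(t) = D·t·e^(φ₁t) + A·(1 − e^(−φ₂t)),

  where x is the Shannon displacement from the pre-disturbance baseline,
  D the perturbation strength, A the new-equilibrium displacement
  (asymptote), and φ₁ < 0, φ₂ the decay/approach rates. The model is fitted
  in a Bayesian framework (uniform box priors, Gaussian likelihood,
  half-normal prior on the noise sd) with a self-contained affine-invariant
  ensemble MCMC sampler; posterior medians, 95% credible intervals, and the
  skewness of the asymptote's marginal summarize each fit.
- **New-equilibrium regressions.** OLS of overall-community dissimilarity
  from the initial state on the rare:abundant abundance ratio.
- **Synthetic community generator.** A lognormal species-abundance
  distribution with multinomial read sampling reproduces the mesocosm
  layout (2 soils × 5 treatments × 5 timepoints × 4 replicates), the
  heavy-tailed partitioning of OTUs into abundance classes, disturbance
  scenarios with taxon-group log-fold effects and invading OTUs, and noisy
  impulse-response diversity trajectories — so every stage of the pipeline
  is testable without sequencing data.

## Worked example

```r
library(rarestab)

cfg <- community_config(seed = 11)              # 20,000 OTUs, depth 10,000
ini <- generate_initial_community(cfg)
tab <- simulate_disturbance_series(ini, default_scenarios(), cfg)

rel <- relative_abundance(subset_samples(tab, tab$metadata$soil == "NCF"))
a   <- classify_taxa(subset_samples(rel, rel$metadata$timepoint == "initial"),
                     soil = "NCF")
table(a$category[a$category != "NEW"])
#>  AAT  CAT  CRT   MT
#>    7    1 4390  958
```

Eight of 5,356 observed OTUs (0.15%) are abundant and 82% are rare — the
partitioning such soils show. (At depth 10,000 a single read is already
0.01%, so every rare OTU is conditionally rare; ART appears at deeper
sequencing.) Fitting the recovery model to the heat-treatment trajectories
of the abundant subcommunity:

```r
res <- run_pipeline(run_config(synthetic = community_config(seed = 11),
                               fit_treatments = "HE",
                               stability = fit_config(seed = 1)),
                    stages = c("classify", "diversity", "stability"))
subset(res$stability_summary, soil == "NCF" & group == "abundant")
#>   soil    group treatment parameter  median    lower   upper skewness_A
#> 1  NCF abundant        HE         D  0.0615  0.00188  0.4473      -2.41
#> 2  NCF abundant        HE         A -0.2792 -1.12635 -0.1937      -2.41
#> 3  NCF abundant        HE      phi1 -0.2254 -1.94063  0.3573      -2.41
#> 4  NCF abundant        HE      phi2  1.4921  0.51364  1.9858      -2.41
#> 5  NCF abundant        HE     sigma  0.0388  0.02816  0.0588      -2.41
```

The asymptote's 95% credible interval lies below zero: the abundant
subcommunity settled at persistently lower diversity — a new equilibrium —
while the ambient control stays at x ≈ 0. Its negative skew means most of
the posterior mass leans toward even deeper displacement.

The full analysis is laid out as numbered drivers:

```sh
Rscript analysis/01_simulate.R       # synthetic mesocosm data -> results/data/
Rscript analysis/02_classify.R       # categories + Sankey shares
Rscript analysis/03_diversity.R      # Shannon + LRR + t tests
Rscript analysis/04_beta.R           # PCoA, PERMANOVA, SIMPER, dissimilarity
Rscript analysis/05_diff_abundance.R # NB Wald responsive OTUs
Rscript analysis/06_stability.R      # Bayesian recovery fits
Rscript analysis/07_equilibrium.R    # ratio-vs-dissimilarity regressions
```

Each writes tidy TSVs under `results/` and prints its headline numbers
(e.g. responsive-OTU ranking HE > FL > DR > FR > AMB; rare taxa carrying
~57% of the overall between-community dissimilarity vs ~8% for abundant
taxa on the default synthetic scenario).

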