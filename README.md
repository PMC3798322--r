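# metamodule

Multi-cohort survival meta-analysis and seed-gene co-expression modules
for tumor transcriptomics.

## What problem this solves

Recurrently amplified chromosomal loci (such as 1q in breast cancer)
contain hundreds of genes; only a few drive patient outcome, and no single
expression cohort is large or clean enough to identify them reliably.
`metamodule` is for analysts who have several independent genes × samples
expression cohorts with survival annotation and want to:

1. **screen** a locus gene set for genes whose expression predicts
   survival *consistently across cohorts*,
2. **expand** a surviving candidate (seed) into its co-expression module,
3. **score** up/down-tag pathway signatures against the profiles and
   relate activation to the seed, and
4. **export** a connectivity-map-style drug-reversal query from a
   seed-high vs seed-low differential-expression contrast.

The statistical core: per-cohort Cox regression on unit-SD-standardized
expression, pooled with the DerSimonian–Laird random-effects estimator

τ² = max(0, (Q − (K−1)) / (Σwₖ − Σwₖ²/Σwₖ)),  w*ₖ = 1/(vₖ + τ²),
β̂_RE = Σw*ₖβₖ / Σw*ₖ,  SE_RE = (Σw*ₖ)^(−1/2),

applied identically to log-hazard ratios (vₖ = SEₖ²) and to Fisher-z
transformed Pearson correlations (vₖ = 1/(nₖ−3)).  A gene passes the
screen when per-cohort Wald p < 0.005 in ≥ 3 cohorts *and* the pooled
Wald p < 0.005; a gene joins the seed module when pooled r ≥ 0.6 with
combined p < 0.001.  A synthetic multi-cohort generator with a planted
latent-factor module and planted prognostic genes makes the whole
pipeline testable offline.  See the vignette in `vignettes/` for the full
model, parameter rationale and numerical choices.

## Worked example

```r
library(metamodule)

cfg <- sim_config(n_cohorts = 6,
                  samples_per_cohort = c(198, 286, 159, 345, 251, 396),
                  n_genes = 500, module_size = 30,
                  prognostic_genes = c(G0001 = 0.5, G0040 = 0.6),
                  censoring_rate = 0.3, seed = 2024)
bundles <- simulate_cohorts(cfg)

# 1. screen the simulated 1q universe
locus <- attr(bundles, "locus")
universe <- locus$gene[locus$chromosome == "1" & locus$arm == "q"]
screen <- screen_locus(bundles, universe)
head(screen, 5)
#>    gene beta_re   hr     tau2 p_combined k n_sig_cohorts passes
#> 1 G0040   0.527 1.69 0.000000   1.21e-61 6             6   TRUE
#> 2 G0001   0.388 1.47 0.000000   1.59e-34 6             6   TRUE
#> 3 G0007   0.310 1.36 0.000000   2.42e-23 6             5   TRUE
#> 4 G0003   0.321 1.38 0.000781   9.11e-23 6             6   TRUE
#> 5 G0023   0.300 1.35 0.000000   4.43e-22 6             5   TRUE

# 2. expand the seed into its co-expression module
mod <- define_module(bundles, "G0001")
mod
#> <module_def> seed G0001: 29 member(s) at r_pooled >= 0.6, p < 0.001 (499 genes tested)

# 3. module score + survival stratification in one cohort
ms <- module_score(bundles[[1]], mod)
km_stratify(bundles[[1]], ms)$p
#> [1] 3.65e-06

# 4. seed-stratified DE contrast -> reversal query
st <- stratify_by_gene(bundles[[1]], "G0001")          # >60% vs <10%
de <- differential_expression(bundles[[1]], st$high, st$low)
q  <- export_query(de, max_per_list = 100)
lengths(q[c("up_list", "down_list")])
#>   up_list down_list
#>        37        13
```

Reading the output: `G0040` (planted at log-HR 0.6/SD) and the module
seed `G0001` top the screen with pooled hazard ratios 1.69 and 1.47 per
expression SD and negligible between-cohort heterogeneity (τ² ≈ 0); the
29 recovered module members are exactly the 29 planted co-expressed
genes; the module's median split separates survival at p ≈ 4 × 10⁻⁶; and
the seed-high arm yields a 37-up / 13-down reversal query.  Correlated
module genes also pass the survival screen — they share the seed's
prognostic latent factor, which is precisely the behaviour the module
concept exploits.

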