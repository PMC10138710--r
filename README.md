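# guildnet

Weighted co-abundance network analysis and causal mediation for small
multi-omics microbiome cohorts.

## The problem

In inflammatory bowel disease, diet plausibly influences mucosal
inflammation *through* the gut ecosystem: adherence to a Mediterranean-style
diet shifts microbial taxa and their metabolites, which in turn shift fecal
calprotectin (FCP), the standard stool biomarker of intestinal inflammation
(< 100 mcg/g consistent with remission, > 250 with active disease). Testing
that idea on a small ulcerative-colitis cohort means integrating several
hundred heterogeneous features per participant — taxa relative abundances,
serum metabolite intensities, short-chain fatty acid and bile acid
concentrations, diet variables — and asking which *groups* of co-varying
features sit on the causal path between a Mediterranean diet score (MDS,
0–13) and FCP.

guildnet implements that analysis as a reusable, tested pipeline:

- **Co-abundance network**: `conet()` builds a weighted network from the
  Spearman correlation of all features with soft-thresholding power
  β (default 10; `soft_threshold_scan()` reports the scale-free fit R² over
  β = 1..20), detects modules by average-linkage hierarchical clustering
  with an adaptive, modularity-guided tree cut (minimum module size 11),
  summarizes each module by its eigengene (first principal component),
  merges modules whose eigengene dissimilarity 1 − cor falls below 0.25,
  and refines membership with signed kME ≥ 0.30.
- **Module–trait association**: Spearman tests of eigengenes and features
  against MDS and FCP with the reporting tiers `*` (p < 0.05), `@`
  (0.05 ≤ p < 0.10), `N`.
- **Risk co-abundant groups (CAGs)**: PAM enterotyping of the baseline
  microbiome on the Jensen–Shannon distance, dominant taxa by
  Kruskal–Wallis at prevalence ≥ 10 % and FDR ≤ 0.1, risk labels from
  baseline FCP, and hypergeometric module enrichment.
- **Mediation cascade**: product-of-coefficients causal mediation with
  quasi-Bayesian intervals — ACME = a·b, ADE, total = ACME + ADE — for
  single mediators (`mediate()`), joint mediator sets (`mediate_joint()`,
  combined ACME = Σ aⱼbⱼ), multi-step chains (`mediate_chain()`), and
  module eigengenes, assembled into a directed acyclic association graph
  (`module_mediation_network()`, `feature_mediation_network()`).
- **Synthetic cohorts with planted truth**: `generate_cohort()` emulates a
  29-participant two-trajectory cohort (13 FCP-increase / 16 FCP-decrease,
  551 features, 10 latent modules, 3 enterotypes, planted diet→guild→FCP
  chains) so every stage can be validated against known ground truth.

## A worked example

Generate the default synthetic cohort, fit the network, associate modules
with the traits, and estimate the planted guild's joint mediation effect:

```r
library(guildnet)

coh <- generate_cohort(cohort_config(seed = 7))
coh
#> synthetic_cohort: 29 samples (13 increase / 16 decrease), 551 features
#>   planted modules: 10 (+ 165 unassigned features); enterotypes: 3
#>   planted chains: guild (ACME -1)

fit <- conet(coh$features, scan_powers = FALSE)
fit
#> conet fit: 551 features -> 13 modules (418 classified, 133 unclassified)
#>   power = 10 (unsigned, spearman), min module size 11, merge diss 0.25, kME >= 0.30
#>   module sizes:
#>   turquoise        blue       brown      yellow       green         red
#>          66          41          40          39          38          38
#>   ...

adjusted_rand_index(coh$truth$modules[names(fit$labels)], fit$labels)
#> [1] 0.601    # at the study's n = 29; ~0.86 at n = 60

assoc <- associate_traits(fit$eigengenes,
                          data.frame(MDS = coh$traits$MDS,
                                     FCP = log(coh$traits$FCP_week8)))
head(assoc[order(assoc$p_value), ], 4)
#>       entity trait        rho      p_value tier
#>         blue   MDS  0.7491243 2.933587e-06    *
#>         blue   FCP -0.4241379 2.184532e-02    *
#>  greenyellow   FCP -0.4014778 3.087550e-02    *
#>          tan   FCP -0.3280788 8.229832e-02    @
```

The `blue` module captures the diet-driven latent factor: positively
associated with the diet score and negatively with inflammation. The
planted seven-feature guild (3 taxa + 4 serum metabolites, true joint
indirect effect −1 on the log-FCP scale) is recovered by joint mediation,
with taxa entered as log relative abundances:

```r
meds <- coh$truth$chains[[1]]$mediators
m <- coh$features$values[, meds]
m[, grepl("^taxon\\.", meds)] <- log(m[, grepl("^taxon\\.", meds)])
f <- mediate_joint(coh$truth$x_std, m, log(coh$traits$FCP_week8),
                   covariates = cbind(inc = coh$traits$trajectory == "increase"),
                   n_sims = 1000, seed = 7)
f
#> mediation (n = 29, 1000 sims):
#>   ACME   -1.541  [-3.127, -0.1859]  p = 0.026
#>   ADE    0.5905   total -0.9509   prop. mediated 1.621

planted_acme(coh$config, "guild")
#> [1] -1
```

The interval covers the planted −1 and excludes zero: a better diet lowers
inflammation through the guild. (At n = 29 the point estimate is noisy and
the proportion mediated can exceed 1 when the direct path's sign opposes
the indirect one — both honest features of cohorts this small.)

The whole pipeline — assembly, network, traits, CAGs, screening, mediation,
cascade — runs end-to-end and writes a hashed manifest:

```r
manifest <- run_pipeline(list(seed = 7), out_dir = "results/run1")
```

## Documentation

The methods vignette (`vignettes/guildnet-methods.Rmd`) describes the
network model, the mediation estimator, the synthetic-data generative model
and its deliberate simplifications, and every numerical choice (binning,
thresholds, tie handling, degenerate inputs) in detail.
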