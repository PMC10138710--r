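---
title: "Co-abundance networks and mediation cascades: models and methods"
author: "guildnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-abundance networks and mediation cascades: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

guildnet analyses small multi-omics cohorts in which a diet-adherence score
is suspected to influence a mucosal inflammation marker through the gut
ecosystem. The motivating design is an ulcerative-colitis cohort observed at
two time points: participants are split by whether fecal calprotectin (FCP,
mcg/g of stool) rose or fell over eight weeks, and each participant carries
several hundred heterogeneous features — microbial taxa as relative
abundances, serum metabolite intensities, fecal short-chain fatty acid and
bile acid concentrations, and dietary variables (daily totals, per-1000-kcal
energy-adjusted values, food-group frequencies) — alongside a Mediterranean
diet score (MDS) on a 0–13 scale (the 14-item screener with the alcohol
point removed, alcohol being contraindicated in IBD).

The analysis has four stages, each exposed as ordinary functions and driven
end-to-end by `run_pipeline()`:

1. **Weighted co-abundance network** (`conet()`): Spearman correlation over
   all features, soft-thresholded adjacency, hierarchical module detection,
   module eigengenes, eigengene-based merging, and signed module membership
   (kME) with refinement.
2. **Module–trait association** (`associate_traits()`,
   `species_trait_screen()`): Spearman tests of eigengenes and individual
   features against MDS and FCP, with the reporting tiers `*` (p < 0.05),
   `@` (0.05 ≤ p < 0.10), `N` otherwise.
3. **Risk co-abundant groups** (`enterotype()`, `dominant_taxa()`,
   `classify_risk()`, `module_cag_enrichment()`): partitioning-around-medoids
   enterotyping of the baseline microbiome on the Jensen–Shannon distance,
   Kruskal–Wallis screening of cluster-dominant taxa (prevalence ≥ 10 %,
   BH FDR ≤ 0.1), risk labels from baseline FCP, and hypergeometric
   enrichment of risk taxa in network modules.
4. **Mediation cascade** (`mediate()`, `mediate_joint()`, `mediate_chain()`,
   `screen_candidates()`, `module_mediation_network()`,
   `feature_mediation_network()`): product-of-coefficients causal mediation
   with quasi-Bayesian intervals, over single features, joint feature sets,
   multi-step chains, and module eigengenes, assembled into a directed
   acyclic association graph.

# The network model

For features $i, j$ the network weight is the soft-thresholded Spearman
correlation, $a_{ij} = |\rho_{ij}|^\beta$ (unsigned, the default) or
$a_{ij} = ((1+\rho_{ij})/2)^\beta$ (signed). The default power is
$\beta = 10$; a power scan (`soft_threshold_scan()`) reports the scale-free
topology fit $R^2$ and mean connectivity for $\beta = 1,\dots,20$ so that 10
or 11 — both defensible for data of this shape — can be chosen explicitly,
and `conet()` notes the ambiguity when either is used.

**Scale-free fit.** Connectivities $k_i = \sum_j a_{ij}$ are placed in 10
equal-width bins; $\log_{10}$ of the bin frequency is regressed on
$\log_{10}$ of the bin-mean connectivity and the fit's $R^2$ reported.
Equal-width binning is used deliberately: with equal-occupancy bins every
bin frequency is identical by construction, which makes the regression
degenerate and the fit index meaningless. An all-equal connectivity vector
yields `NA`, not an error.

**Module detection.** Features are rank-transformed (matching the Spearman
geometry), standardized, and clustered by average-linkage hierarchical
clustering on the Euclidean distance between profiles (a
topological-overlap-dissimilarity input is available behind
`clustering_input = "tom"`). The tree is cut adaptively: candidate heights
are scanned, clusters below `min_module_size` (default 11) dissolve to
singletons, and the lowest height whose weighted Newman modularity on the
adjacency comes within 1 % of the maximum is chosen. The near-maximum rule
matters: modularity keeps creeping up by tiny increments as weakly attached
features are absorbed, so taking the literal maximum pads modules with
noise, while the lowest near-maximal height keeps them tight. A qualifying
cluster must additionally be more cohesive than chance: its mean within-
cluster $|\rho|$ must exceed twice $\sqrt{2/\pi}/\sqrt{n-1}$, the expected
absolute correlation of independent features at sample size $n$. Without
this floor, average linkage of pure-noise features happily forms large
"modules" whose members correlate only as much as chance allows; with it, a
pure-noise table comes back fully unclassified. A fixed cut height is
available (`cut_height`) for users who want the classical static cut.

**Eigengenes and membership.** A module eigengene is the first principal
component of the module's z-scored feature submatrix, unit-variance scaled
and sign-oriented along the module's mean profile. When the network is
Spearman-based, eigengenes summarize the rank-transformed profiles: the
feature blocks live on wildly different scales (compositional fractions,
log-normal concentrations, centred intensities), and ranks are the one
common scale the network itself uses. Modules whose eigengenes correlate
above $1 - 0.25$ are merged iteratively (average-linkage tree over
$1-\mathrm{cor}$, cut at `me_diss_threshold` = 0.25, eigengenes recomputed
each round until no pair remains below threshold). Membership is
$kME(f, m) = \mathrm{cor}(\text{feature } f, ME_m)$; features whose
own-module membership falls below 0.30 (strictly — 0.30 itself is retained)
move to the unclassified set, and modules pushed below the minimum size by
refinement dissolve. Refinement runs after merging; the order is logged in
the fit object.

# Mediation

`mediate()` implements linear-model product-of-coefficients mediation: the
mediator model $M = \alpha_1 + aX (+\text{covariates})$ and outcome model
$Y = \alpha_2 + cX + bM (+\text{covariates})$ are fitted by least squares;
ACME $= ab$, ADE $= c$, and in this no-interaction setting
$\text{ACME} + \text{ADE} = \text{total}$ exactly (asserted to $10^{-8}$ in
the tests). Uncertainty is quasi-Bayesian: `n_sims` coefficient vectors are
drawn from each model's asymptotic normal distribution, the ACME recomputed
per draw, the interval taken as the percentile interval and the p-value as
$2\min(P(\text{draws} \le 0), P(\text{draws} \ge 0))$. Everything is
deterministic under a fixed seed. `mediate_joint()` regresses each mediator
on the exposure separately and the outcome on the exposure and all
mediators jointly; the combined ACME is $\sum_j a_j b_j$ with per-mediator
contributions reported. `mediate_chain()` evaluates ordered
exposure–mediator–outcome triples, where one step's outcome may be the next
step's exposure, and rejects cyclic specifications.

Guards: exposure–mediator collinearity (condition-number check), constant
inputs, fewer than 100 draws, $n < 10$, and mediator sets of $n/2$ or more
are rejected. The proportion mediated is ACME/total, reported as `NA` when
the total is near zero or of opposite sign to the ACME — the ratio is not
meaningful there.

In the cascade, mediation edges are kept when the ACME interval excludes
zero; no multiplicity correction is applied across edges beyond the
per-edge intervals, matching common practice of reporting raw mediation
p-values, and this is stated rather than hidden. Candidate screening
applies BH separately within the diet-score family and the inflammation
family (FDR ≤ 0.20, inclusive), with `mode = "any"` or `"both"` for
admission by one or both traits. The module-level network pre-filters
source–sink pairs by a marginal Spearman screen at p < 0.10 before testing
every other module's eigengene as mediator, and the assembled graph is kept
acyclic by construction.

# The synthetic cohort generator

`generate_cohort()` is first-class, tested code: it produces cohorts with
known module structure, known enterotypes and known mediation effects, so
every stage can be validated against ground truth without any external
download. The default configuration emulates the motivating study: 29
participants (13 FCP-increase, 16 FCP-decrease), 551 features in seven
blocks (331 taxa, 84 serum metabolites, 6 SCFAs, 9 bile acids, 121 diet
variables), 10 latent modules covering about two-thirds of the features,
and three enterotypes.

**Latent model.** A feature in module $k$ is
$z = \lambda F_k + \sqrt{1-\lambda^2 + \sigma^2}\,\epsilon$ with factor
loading $\lambda$ (default 0.8) and extra noise $\sigma$ (default 0.5), so
$\lambda$ is the feature–factor correlation in the $\sigma \to 0$ limit and
two same-module features correlate at $\lambda^2$ there. Unassigned
features are standard normal noise.

**Observation scales.** Taxa are logistic-normal: latent values are
exponentiated and closed to relative abundances per sample (rows sum to 1
by construction). SCFAs and bile acids are log-normal concentrations;
serum metabolites and diet variables stay on a centred continuous
(log-intensity-like) scale. The closure is a deliberate stand-in for
relative-abundance structure; it is not a sequencing count model.

**Enterotypes.** Each of three community types has eight signature taxa
with a high baseline abundance (latent +2.5) and a further +2.5 shift in
their own type — mirroring how real enterotypes are defined by dominant
driver genera. The contrast is calibrated so the planted types are
unambiguous (PAM on Jensen–Shannon recovers them at ARI 1.0 across seeds);
baseline FCP carries a community-type gradient (the first type is the
high-inflammation one) applied at both time points.

**Diet score and FCP.** MDS is drawn as Binomial(13, plogis(0.9 F₁)), an
integer 0–13 tied to the first latent factor so one module is genuinely
diet-associated. FCP is log-normal: week-8 log FCP is
$\mu_8(\text{trajectory}) + \text{enterotype shift} + cX_{std} +
\sum_j b_j M_j + \varepsilon$, with the trajectory gap (default 2.9 on the
log scale) matching a 961 vs 53 mcg/g contrast, and baseline log FCP uses a
moderate trajectory split (4.7 vs 6.3) so that enterotype medians stay
unimodal. Order-consistency between the two time points is enforced on the
log scale, where ties have probability zero; an early floored-at-zero
variant truncated the log outcome and biased planted-effect recovery, which
is why FCP is strictly positive log-normal instead.

**Planted chains.** Path coefficients are per standard deviation of the
exposure: each mediator is $a_j X_{std}$ plus unit noise, and the outcome
receives $\sum_j b_j M_j$ where $M_j$ enters *as observed* — log relative
abundance for taxa, log concentration for SCFAs/bile acids, the raw scale
elsewhere (centred so the FCP location stays at its design mean). Planting
on the observed scale matters: if the outcome responded to pre-closure
latent values, the compositional log-sum term would act as an omitted
variable and attenuate recovery of the planted effect by roughly 10 %.
Biologically this choice says the host responds to the relative abundance
actually present in the gut. The default chain is a seven-feature guild
(3 taxa + 4 serum metabolites) with joint indirect effect
$\sum_j a_j b_j = -1$ on the log-FCP scale; `planted_acme()` returns the
oracle value for any chain.

**What the generator does not emulate.** Phylogenetic correlation among
taxa, sequencing-depth and count noise, longitudinal dynamics beyond two
time points, covariation between diet and medication, and realistic
block-specific missingness. Passing the recovery tests therefore shows the
estimators are correct and calibrated on data with this covariance
geometry, not that the pipeline will find true structure in any real
cohort of 29 participants — at that sample size the paper-scale analysis is
hypothesis-generating, and so are analyses run with this package.

# Numerical and design choices

- **Per-block feature counts** (331/84/6/9/121) are an invention: only the
  total (551) and the block kinds are fixed by the motivating design; the
  split follows the relative sizes such panels typically have.
- **FCP clinical bins**: < 100 remission, 100–250 grey zone (both
  boundaries inclusive, reading the printed interval inclusively), > 250
  active.
- **Trajectory ties** (week-8 FCP exactly equal to baseline) are rejected
  with a distinct error: the cohort design keeps only participants whose
  FCP changed.
- **Missing values** at assembly: a feature with more than 20 % missing is
  dropped (logged); below that, median imputation. Constant features are
  dropped with a warning before correlation, which cannot rank them.
- **Spearman p-values** use exact computation for $n \le 9$ and the
  t-approximation otherwise; kME uses Pearson correlation on the
  (rank-transformed, when Spearman) profiles.
- **Enterotype distance** defaults to the square root of the
  Jensen–Shannon divergence (the enterotyping-literature convention);
  Bray–Curtis is available by `distance = "bray"`. `k` is chosen from 2–6
  by average silhouette width; three clusters is an outcome of the data,
  never an input.
- **Enrichment** is a one-sided hypergeometric over-representation test
  over the classified-taxa universe with BH correction across
  module × risk-set pairs, flagged at q ≤ 0.1.
- **PERMANOVA** permutes group labels (999 by default) with the
  $(\text{hits}+1)/(n_{perm}+1)$ p-value convention; single-factor only.
- **Robust regression** is Huber M-estimation (c = 1.345) by iteratively
  reweighted least squares.
- **Determinism**: every stochastic stage takes a seed, `run_pipeline()`
  derives per-stage seeds from the global one, and rerunning with the same
  configuration reproduces identical output hashes (asserted in the tests).
- **Problem sizes** in the test-suite simulations — 29- and 60-sample
  cohorts, a few hundred replicates for calibration checks, 199–999
  permutations — are chosen to estimate each property's pass/fail status
  with comfortable Monte-Carlo margins while keeping the default test run
  quick on a laptop.

# Known limitations

The mediation machinery is linear with no exposure–mediator interaction,
no binary/count outcome links, and no sensitivity analysis for unmeasured
confounding; compositional mediators are handled by log transformation,
which removes most but not all closure-induced coupling (centred log-ratio
and normalizer-covariate variants behave similarly in our checks). Network
construction is single-cohort and in-memory (no blockwise mode for very
large feature sets). The adaptive cut is a pragmatic, modularity-guided
procedure — it is deliberately simple, and on real data a practitioner
should inspect the dendrogram and the power scan rather than trust any cut
blindly.
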