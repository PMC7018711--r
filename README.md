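# burstlab

Macroevolutionary analysis of fossil clades from discrete character
matrices, stratigraphic ranges and continuous traits: time-binned
morphological disparity, morphospace ordination and separation tests,
Bayesian fossil-tree time-scaling, per-bin rates of discrete character
evolution, and variable-rates Brownian-motion modelling of a continuous
trait with Bayes-factor model comparison. A synthetic-data module generates
every input with known ground truth, so the whole workflow is testable
without external downloads.

The package is aimed at palaeobiologists asking the classic "early burst"
question: did a clade reach maximal morphological variety and its fastest
rates of change early in its history, and did later evolution stagnate?

## The quantities at the core

**Disparity.** A discrete character matrix (taxa x characters, with
missing/inapplicable codes and polymorphisms) is converted to a pairwise
dissimilarity matrix `D` with a comparable-character count matrix `C`.
The headline metric is the maximum observable rescaled distance (MORD):
per pair, the summed character differences divided by the summed maximum
attainable difference of the characters both taxa code, bounded in [0, 1].
Per time bin, disparity is the mean pairwise distance, optionally weighted
by comparability:

    weighted disparity = sum(D_ij * C_ij) / sum(C_ij)   over member pairs,

with 95% confidence intervals from 500 taxon bootstrap replicates.
Morphospaces come from principal coordinates analysis with optional
Cailliez or Lingoes negative-eigenvalue correction; separation between
bins is tested by pairwise PERMANOVA and disparity differences by Welch
t-tests, both with Benjamini–Hochberg false-discovery-rate control.

**Discrete character rates.** On a time-scaled tree, ancestral states are
reconstructed per character under an equal-rates Mk model and each branch
accumulates its expected number of changes; per bin, a Poisson
likelihood-ratio test compares the bin's rate `lambda_bin` (changes per
character-my) against the pooled rate, classifying bins as significantly
`high`, `low` or `ns` after FDR adjustment.

**Trait rates.** A continuous trait (log10 skull length) is modelled by
variable-rates Brownian motion: reversible-jump MCMC places multiplicative
rate scalars on branches or whole clades, stepping-stone sampling gives
marginal likelihoods for the homogeneous and variable-rates models, and

    logBF = 2 * (logZ_variable - logZ_homogeneous)

is read with the conventional bands (>5 strong, >10 very strong evidence
for rate heterogeneity).

**Time-scaling.** Tip ages are drawn uniformly from stratigraphic ranges;
node ages come either from minimum-branch-length scaling or from Bayesian
outgroup dating, which propagates uniform divergence densities over a
ladder of successively older outgroup ages by numerical quadrature.

## Worked example

```r
library(burstlab)

# synthetic study with known ground truth: 115 taxa, 250 characters,
# early-burst rates planted on the oldest third of the tree
sc <- simulate_scenario(seed = 1)

d   <- morph_distance_matrix(sc$matrix, "mord")
tr  <- trim_distance_matrix(d)          # 13 taxa removed (no shared chars)
dts <- disparity_through_time(tr$dist, sc$ranges, sc$bins,
                              n_boot = 500, seed = 1)
head(dts[!is.na(dts$estimate), c("bin", "n", "estimate", "ci_lo", "ci_hi")], 5)
#>            bin n estimate  ci_lo ci_hi
#> 8  181.3-171.3 4   0.0942 0.0161 0.182
#> 9  171.3-161.3 2   0.1081 0.1081 0.108
#> 10 161.3-151.3 3   0.1415 0.0000 0.224
#> 11 151.3-141.3 5   0.1602 0.0968 0.228
#> 12 141.3-131.3 6   0.2770 0.2131 0.340
```

Each row is a 10-my bin (ages in Ma): `n` taxa overlap the bin, `estimate`
is their mean pairwise MORD dissimilarity and the interval is the 2.5–97.5
percentile of 500 bootstrap replicates (the oldest bins of a birth–death
clade hold too few taxa to appear; the synthetic generator plants early
*rates*, not an early taxonomic radiation).

Detecting planted rate heterogeneity in a continuous trait:

```r
tree <- simulate_tree(60, birth = 0.05, death = 0.02, span = 160, seed = 7)
scal <- plant_clade_scalars(tree, n_tips_clade = 10, r = 10)
tv   <- simulate_trait_vr(tree, sigma2 = 0.02, scalars = scal, seed = 8)
cfg  <- vr_config(iterations = 20000, burn_in = 5000, thinning = 20)
post <- vr_mcmc(tree, tv$trait, cfg, seed = 9)
mean(post$mean_scalars[scal > 1]); mean(post$mean_scalars[scal == 1])
#> [1] 4.58
#> [1] 1.33

z1 <- stepping_stone(tree, tv$trait, "variable", k_stones = 28,
                     iters_per_stone = 2000, seed = 10, config = cfg,
                     init_state = post$final_state)
z0 <- stepping_stone(tree, tv$trait, "homogeneous", k_stones = 28,
                     iters_per_stone = 2000, seed = 11, config = cfg)
bayes_factor(z1$log_evidence, z0$log_evidence)
#> $logBF
#> [1] 13.62624
#> $evidence
#> [1] "very strong"
```

The posterior mean rate multiplier inside the planted clade (4.6) exceeds
the outside mean (1.3), and the Bayes factor reads the 10x heterogeneity
as very strong evidence against the homogeneous model.

The full multi-stage analysis can also be driven from a single config:

```sh
Rscript scripts/pipeline.R config.yaml
```

which writes per-stage CSV/Newick outputs plus an md5 manifest (see
`?run_config` for the keys).

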