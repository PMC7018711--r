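---
title: "Models and methods for disparity and evolutionary-rate analyses of fossil clades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for disparity and evolutionary-rate analyses of fossil clades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burstlab)
```

This vignette explains the models behind burstlab, the parameters that
matter, the numerical choices, and what the synthetic-data module does and
does not emulate. It states no empirical result beyond what the package's
tests and acceptance script themselves compute.

## 1. From character matrices to distances

A cladistic matrix codes taxa for discrete skeletal characters; cells may
be missing or inapplicable (both treated as "no comparison possible" — the
distance construction gives no reason to distinguish them) or polymorphic
(a set of states; distances use the minimum over cross-pairs of states, the
standard convention for cladistic distances). Per-character differences
are 0/1 for unordered characters and the minimum absolute state difference
for ordered ones.

Four pairwise metrics are offered. Gower (GOW) divides the summed
differences by the number of comparable characters. The maximum observable
rescaled distance (MORD) instead divides by the summed *maximum attainable*
difference of the comparable characters: 1 for an unordered character with
at least two observed states, the observed state range for an ordered
character, and 0 for a character invariant across the matrix, which
therefore drops out of numerator and denominator alike. The observed (not
theoretical) range is recomputed per matrix — that is what "maximum
observed" means — so MORD is bounded in [0, 1] and robust to incomplete
taxa. Raw Euclidean (RAW) and generalised Euclidean (GED) distances are
kept for comparison; GED imputes the grand-mean per-character difference
into non-comparable cells, which makes it defined for every pair but also
means two identically-coded incomplete taxa have nonzero GED — a property
of the metric, not a bug, and one reason MORD is the default. Character
weights are all 1; no weighting block is honoured.

Pairs sharing no characters are undefined under RAW/GOW/MORD.
`trim_distance_matrix()` removes taxa greedily — always the taxon involved
in the most undefined pairs, ties broken toward the least complete taxon,
then lexicographically — until the matrix is fully defined. On small random
instances the greedy order matches the brute-force maximum retained set
(verified in the tests up to 7 taxa); this is not guaranteed in general,
but adversarial conflict graphs do not arise from realistic missingness
patterns.

## 2. Ordination and its corrections

Principal coordinates analysis double-centres `-D^2/2` and
eigendecomposes. Distances from incomplete discrete data are usually
non-Euclidean, producing negative eigenvalues; the Cailliez correction
(default choice when one is wanted) adds the smallest constant to all
off-diagonal distances making the configuration Euclidean, while Lingoes
adds a constant to the squared distances. Axes with eigenvalue magnitude
below `1e-10` of the largest are dropped as numerical zeros. Variance
percentages divide each retained eigenvalue by the sum of *positive*
eigenvalues, so an uncorrected ordination's percentages ignore the
negative part of the spectrum and a corrected ordination — whose summed
eigenvalues are inflated by the constant — reports visibly smaller leading
percentages. Because nothing in a figure caption usually says which
convention was used, the package reports the uncorrected ordination by
default and leaves the correction explicit in the API.

## 3. Time bins, membership and disparity

Two binning schemes: eight Mesozoic epoch-level bins, and equal-length
bins (default 10 my) laid from the oldest boundary downward; with the
default span (251.3 to 93.9 Ma) the equal scheme yields 16 bins with a
boundary exactly at the Triassic–Jurassic boundary (201.3 Ma). A taxon
joins every bin its stratigraphic range overlaps with positive measure —
range-through membership, chosen because taxa genuinely spanning a
boundary belong in both neighbouring bins; a point range on a boundary
goes to the younger bin only. The overlap rule is a documented choice:
point dating (one draw per taxon) is equally defensible but makes bin
membership stochastic.

Per-bin disparity is the mean pairwise distance over member pairs, or the
comparability-weighted version `sum(D*C)/sum(C)`, which damps the noise
contributed by poorly-overlapping pairs. Confidence intervals are 2.5–97.5
percentiles of 500 bootstrap replicates resampling *taxa* with replacement
(the standard disparity protocol; resampling pairs would break the
exchangeable unit). Resampled slot pairs that point at the same original
taxon are excluded so duplicates do not drag estimates toward zero. Bins
with fewer than two members are reported as missing rather than zero.
Rarefaction (subsampling without replacement at fixed size) asks whether a
disparity difference is a sample-size artefact; the sum of variances is
nearly invariant under rarefaction, which the tests verify.

## 4. Morphospace and disparity hypothesis tests

Between-bin separation uses one-factor PERMANOVA on the bin-pair submatrix
of distances: pseudo-F from total and within-group sums of squared
distances, significance from label permutations with the observed
labelling counted. All distinct assignments are enumerated when there are
at most 10 000 (so small designs get exact p-values; a separated 3+3
design bottoms out at p = 2/20); otherwise 999 Monte-Carlo permutations
are drawn. Taxa falling in both bins of a pair (range-through taxa in
adjacent bins) are excluded from that comparison — with duplicated rows
the group labels would no longer be exchangeable. Disparity differences
use two-sided Welch t-tests whose sample unit defaults to the within-bin
pairwise distances; per-bootstrap-replicate metric values can be supplied
instead (`unit = "bootstrap"`) since the right unit is genuinely
ambiguous. All p-value families are Benjamini–Hochberg adjusted. Note BH
is monotone and never below the raw p, but re-applying it to already
adjusted values is not a no-op in general.

## 5. Time-scaling fossil trees

Point tip ages are drawn uniformly from each taxon's [LAD, FAD] interval,
independently per tree replicate, so a dated tree sample carries both
topological and dating uncertainty.

The minimum-branch-length dater starts every node at its oldest descendant
tip age and pushes parents older until each branch lasts at least
`min_length` (default 1 my).

The Bayesian outgroup dater treats each internal node's age as the
innermost divergence of a ladder. The node's own lower bound is its oldest
descendant observation; walking rootward, each successive divergence is
bounded below by the max-accumulated oldest age of the sister clade at
that ancestor, and beyond the root by the user's outgroup first-appearance
ages (strictly increasing rootward). Conditional on the next divergence
rootward at age `y`, a divergence with bound `b` is uniform on `(b, y)`;
the rootmost is uniform up to a hard ceiling `t0` (default: oldest
outgroup + 20 my — deliberately not a maximum clade-age constraint). The
marginal posterior of the target divergence is obtained by propagating
these conditionals inward on a uniform age grid (default 1000 cells) by
midpoint quadrature; the reported age is the posterior mean. Because nodes
are dated marginally, a postorder pass enforces parent > child by one grid
step where means collide. The recursion is verified against an independent
dense-grid nested quadrature in the tests, and doubling the grid changes
node ages by well under 0.5%. Handling of nodes whose calibrating
"outgroup" is an internal sister clade follows the same rule as true
outgroups: only its oldest observation enters, max-accumulated so the
ladder never decreases rootward.

Batch dating oversamples input trees and keeps the first `n_keep`
successes with a failure log, since outgroup dating can legitimately fail
on pathological tip-age draws.

## 6. Discrete-character rates

Ancestral states come from a symmetric equal-rates Mk model per character;
the transition probability has the closed form
`P(same) = 1/k + (k-1)/k * exp(-k q t)`. The per-character rate `q` is
estimated by maximum likelihood; because the log-likelihood flattens into
a plateau for large `q` (saturation), the optimiser first brackets the
peak on a 25-point log grid and then refines — a blind golden-section
search can stall on the plateau. Marginal node probabilities use the
standard inside/outside two-pass algorithm with a flat root prior,
equivalent to re-rooting at every node; the tests verify them against
brute-force enumeration over all internal state assignments.

Expected changes per branch sum, over the characters scorable on that
branch, the probability that parent and child differ, treating the two
marginal distributions as independent (a documented simplification: the
exact joint would require pairwise marginals; independence is robust to
reconstruction ties and errs toward counting a fraction of a change where
the reconstruction is uncertain). A character is scorable on a branch iff
both ends carry information — tips by direct coding, internal nodes by
having at least one coded descendant. Opportunity is duration times
scorable characters (character-my), and both changes and opportunity are
apportioned across bins by the fraction of branch duration in each.

Per bin, a Poisson likelihood-ratio test compares one pooled rate against
separate bin/rest rates (`LRT = 2(l1 - l0)`, chi-squared with 1 df), with
BH adjustment across bins within each tree — the correction scope is a
package choice since conventions differ — and classification `high`/`low`
by the sign of the rate difference at adjusted p < 0.05. Saturation
matters for power: a burst of rate multiplier `r` on binary characters
caps expected differences at 1/2, so very high `q * t` products compress
the contrast between bins. The acceptance study therefore simulates at a
base rate (0.004 changes/my) where the planted 5x burst stays below
saturation.

## 7. Variable-rates trait model

The trait model is Brownian motion with variance `sigma2` per my on branch
durations multiplied by rate scalars. Scalars live at two kinds of
location: single branches, and internal nodes, where one parameter
rescales the node's stem and entire subtree. Clade locations matter: a
clade-wide rate shift expressed with branch scalars alone needs one
parameter per branch, and the prior cost of ~20 joint parameters roughly
cancels the likelihood gain, leaving genuine shifts undetected by the
marginal likelihood; a single clade scalar restores the intended
behaviour. The effective multiplier of an edge is the product of every
scalar covering it, and reported per-branch rates are posterior means of
that product.

Priors (the model has no canonical defaults, so these are declared):
`sigma2` half-Cauchy with scale 1; scalar values lognormal(0, 1.1), which
puts ~95% of mass in roughly [1/9, 9] and keeps 10x shifts plausible; the
number of active scalars uniform on 0..L over the L locations, which makes
the reversible-jump acceptance for add/delete moves (with the value prior
as proposal) reduce to likelihood and value-prior ratios. Moves: multiplier
updates of `sigma2` and of one active scalar (log-uniform step 0.7), and
add/delete jumps; with the likelihood silenced the sampler provably
returns its uniform prior on the scalar count (chi-squared checked in the
tests). The root state is profiled out by evaluating the likelihood as the
product of the n-1 contrast densities (Felsenstein pruning, compiled in
C++; verified against direct multivariate-normal evaluation).

Desk-scale defaults are 200 000 iterations, 20 000 burn-in, thinning 100 —
the shape, not the length, of a production run of hundreds of millions of
iterations; convergence is summarised by the minimum effective sample size
across `sigma2`, the scalar count and the log-likelihood (a simple
initial-positive-sequence estimator). The tests and acceptance studies use
shorter, explicitly-passed chains sized so that each check's statistic is
stable.

Marginal likelihoods come from stepping-stone sampling along the power
ladder `beta_j = (j/K)^(1/theta)` with `theta = 0.25` (stones concentrated
near the prior, where the integrand varies most), warm-starting each stone
from the last and discarding 10% per stone. The estimator is checked
against a closed-form conjugate-normal evidence. Prior-started ladders
bias the *variable-model* evidence low — a stone's reversible-jump chain
can fail to find the supporting scalar configuration at all — so the
variable-model ladder should be run from the posterior downward
(`descend = TRUE`, warm-started from a converged `vr_mcmc()` state); the
estimator only requires equilibrium samples at each stone, so the
visiting order is free. Bayes-factor studies here use 28 stones of 2000
iterations; for data whose true log Bayes factor sits near a decision
band the remaining run-to-run spread is still one to two log units, which
is worth remembering before reading a single borderline value literally. `logBF = 2 * (logZ_variable -
logZ_homogeneous)`, with >5 strong and >10 very strong.

Rates through time cut each branch at bin boundaries and average scalars
weighted by within-bin duration — shared ancestry is thus reflected only
through branch durations, a documented simplification of post-processing
tools that reweight by phylogeny. The consensus rate tree keeps clades
present in every input tree (strict consensus) and averages their mean
scalars; edges absent from any tree are dropped.

## 8. The synthetic-data module

`simulate_tree()` runs a forward birth–death process conditioned on the
total number of tips, keeps extinct tips as leaves, closes survivors where
the next event would have fallen (so no branch has zero length) and
rescales so the root sits `span` my before the youngest tip age.
`simulate_characters()` evolves Mk characters with optional per-branch
rate multipliers and masks cells per taxon to hit an i.i.d. completeness
target (the 1–95% spread of real matrices; no character-correlation
structure). `simulate_trait_vr()` accumulates Gaussian increments with
variance `sigma2 * r * duration`. `simulate_strat_ranges()` draws FAD/LAD
windows inside each tip's subtending branch. `early_burst_scalars()` and
`plant_clade_scalars()` plant the two heterogeneity patterns: rate
multipliers on all branches older than a cutoff (default: the oldest third
of the tree), and on the most duration-rich clade of ~10 tips.

`simulate_scenario()` fixes the study conditions: 115 taxa, 250 characters,
a 160-my span ending at 91.3 Ma, birth 0.12 / death 0.09 per my (high
turnover, so extinct tips occur throughout the span), completeness 1–95%,
base Mk rate 0.004/my with a 5x burst and base `sigma2` 5e-4 (log10 units
squared per my, giving a realistic ~0.3 spread in log10 skull length) with
a 10x burst, stratigraphic windows up to 5 my, and six outgroup ages
laddered 4 to 40 my above the root. One structural difference from real
fossil data: a homogeneous birth–death clade starts from a single lineage,
so the deepest time bins hold very few taxa and their per-bin disparity is
unstable — the synthetic scenario does not emulate an early taxonomic
radiation, only early elevated rates. The recovery studies use smaller instances chosen
for statistical power at desk scale: 30 tips / 100 characters / three
50-my bins aligned with the burst window for discrete rates (200
replicates), and 60-tip trees grown at birth 0.05 / death 0.02 per my —
low net diversification, so ~10-tip clades are deep enough to carry
evidence — for the variable-rates study (20 replicates).

What passing these tests shows: the estimators recover planted structure
of realistic magnitude at realistic sample sizes, and the samplers agree
with closed forms and brute-force oracles. What they do not show: anything
about correlated character evolution, non-uniform preservation through
time, taxonomic error, or rate patterns other than the planted ones —
real-data conclusions still rest on the usual sensitivity analyses.

## 9. Degenerate inputs and tie-breaks

Missing and inapplicable states are merged; a character losing every coded
cell after masking keeps one. Pairs with no shared characters are NA, not
errors, until trimming. A point stratigraphic range on a bin boundary goes
to the younger bin. Zero-variance t-test samples return t = 0, p = 1 when
means agree (p = 0 otherwise). Bins with no opportunity are missing, not
ns. Equal marginal node ages after outgroup dating are separated by one
grid step. Ties in trimming fall back to completeness, then taxon label.
The MCMC records a rejected impossible move (delete with an empty scalar
set, add with a full one) as a stay, preserving detailed balance.
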