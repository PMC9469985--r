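---
title: "Resolving nested subpopulation centers in continuously distributed populations"
author: "sibpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving nested subpopulation centers in continuously distributed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sibpop)
```

## The problem

Wide-ranging species that occupy continuous habitat rarely fall into
discrete genetic populations.  Isolation by distance (IBD) — the steady
increase of genetic differentiation with geographic distance under limited
dispersal — blurs cluster boundaries, so admixture-type clustering of the
whole sample produces ambiguous memberships and arbitrary splits.  What can
be resolved, even under IBD, are the *cores* of genetic groups: regions
where interpolated cluster membership is decisively high.  `sibpop`
implements a spatial iterative bifurcation process (SIBP) that finds these
"subpopulation centers", together with the supporting machinery a full
analysis needs (format I/O, spatial thinning, diversity and divergence
statistics, spatial autocorrelation, kernel-density center polygons), and
two seeded simulators that generate data with known truth for validation.

## The bifurcation process

Each round applies three steps to the current sample:

1. **Divide** the individuals into K = 2 clusters and estimate each
   individual's membership proportions `q` (rows of the Q matrix sum to 1).
   Several replicate estimates are aligned and averaged (below).
2. **Interpolate** each cluster's membership over space with a thin-plate
   spline, giving a smooth surface of membership probability.
3. **Select**: individuals whose own location evaluates at `>= 0.70` on a
   cluster's surface form that cluster's retained group; everyone else is
   dropped from further rounds.  The boundary value 0.70 is the method's
   single decisive constant: it demands a clear majority (beyond 0.5) with
   a margin against interpolation noise, while not requiring near-fixation.

The two retained groups are bifurcated recursively.  A branch terminates
when neither cluster retains anyone, when a retained group is smaller than
`min_group` (default 10 — below this, membership surfaces are dominated by
single individuals and further division is meaningless), or at the
recursion cap.  A terminal node is reported as a subpopulation center.
When exactly one cluster retains individuals, the node is *also* reported
as a center holding its members not claimed by deeper centers — the nested
outcome in which a large group contains a resolvable sub-core.  Centers are
named by alternating binary tokens: the root splits into `1` and `2`,
their children into `1a|1b` and `2a|2b`, then `1a1|1a2`, and so on, so a
center's name encodes its lineage.

Every stochastic step draws its seed deterministically from the
configuration seed and the node name, so subtree results are independent
of sibling execution order and reruns are bit-identical.

### The membership estimator

Memberships are estimated by a maximum-likelihood admixture model fitted
with block-coordinate EM: each allele copy of individual `i` is drawn from
cluster `k` with probability `q_ik`, and cluster `k` has its own allele
frequencies per locus (independent across loci).  This replaces the
Bayesian MCMC machinery of the classical admixture samplers: it estimates
the same quantity (Q) orders of magnitude faster and deterministically
given a seed.  The frequency update carries a Dirichlet pseudocount of 1
per allele — the posterior-mean update of a flat frequency prior — which
keeps frequencies strictly positive; the EM objective (log-likelihood plus
the frequency penalty) is monotone non-decreasing and convergence is
declared when it changes by less than `tol` (default 1e-6).  Missing calls
contribute nothing to the likelihood.

Replicate variability, which the MCMC samplers obtain from independent
chains, comes from seeded random restarts.  Replicates are aligned with
the standard pairwise similarity statistic
`G = 1 - ||Q1 - Q2||_F / sqrt(2n)`: when the joint permutation space
`K!^(R-1)` is small the alignment is solved exactly, otherwise a greedy
pass against the running mean is restarted over many random replicate
orders.  For K = 2 each per-replicate choice is exhaustive.  The aligned
matrices are averaged and row-renormalized.

A maximum-likelihood estimator differs from a posterior mean in one way
that matters here: on data with *no* structure, the ML fit still converges
to some arbitrary split and assigns confident memberships to it, where the
Bayesian posterior mean would hover near 0.5.  Averaging replicates only
partly repairs this, because alignment deliberately maps arbitrary splits
onto each other.  The bifurcation process therefore uses *cross-fitted*
memberships (`cross_fit = TRUE` in `run_admixture_replicates()`): each
replicate holds out a random half of the loci, learns the clustering on
the remainder, estimates the clusters' allele frequencies at the held-out
loci by weighting individuals with their trained memberships, and
re-estimates every individual's membership from the held-out loci alone
(q-only EM from a flat start with a Dirichlet(1) row smoothing).  A split
that only fits sampling noise does not generalize: its two clusters have
nearly equal held-out frequencies, so cross-fitted memberships collapse
toward 0.5 (observed range about 0.4–0.6 on panmictic validation demes of
50).  A genuine split generalizes and keeps deme-level mean memberships
around 0.8–0.95.  This is the standard cross-fitting cure for
overfitting bias, applied to the membership estimand.

One further degeneracy rule guards the selection step: when every
sample's interpolated membership leans toward the same cluster (minimum
surface value above 0.5), nothing was actually bifurcated — the field is
a flat offset from an unbalanced division, not an isocline partition —
and `bifurcate_once()` retains no one.  A genuine one-sided outcome — a
real minority region that never reaches 0.70 — still has majority samples
on both sides and is unaffected.  The per-node replicate agreement `G` is
reported for auditing; with cross-fitting, spurious extra centers were
not observed over 22 seeded validation draws at 50 individuals per
terminal deme.

### K-selection diagnostics

Although SIBP always divides at K = 2, the package also reports the
standard diagnostics for choosing K in a one-shot analysis: per-K mean and
standard deviation of the replicate objective (the converged
log-likelihood, standing in for the marginal data probability), and the
second-difference statistic
`delta_K = |mean(L(K+1)) - 2 mean(L(K)) + mean(L(K-1))| / sd(L(K))`,
defined at interior K with consecutive neighbors and positive sd.  The
package reports these curves and never auto-selects K — reading a plateau
is a judgment call that belongs to the analyst.

## Spatial interpolation

The interpolator is a thin-plate spline
`f(x) = d0 + d1 x + d2 y + sum_i c_i r_i^2 log r_i` with the smoothing
weight chosen by generalized cross-validation (GCV), mirroring the default
behavior of the kriging tools commonly used for this step.  Properties the
tests pin down: a constant field is reproduced everywhere; affine fields
are reproduced exactly at any smoothing weight; with the weight forced to
0 the spline interpolates the data exactly; and surfaces fitted to
complementary membership columns sum to 1 everywhere (before clipping to
[0, 1]).

One numerical guard matters: the GCV score degenerates as the effective
degrees of freedom approach the sample size (its denominator
`(n - tr A)^2` vanishes), which for spatially incoherent values can select
near-interpolation — exactly the wrong behavior for step 3, which relies
on smoothing to flatten non-spatial structure.  The GCV search is
therefore bounded at `df <= 3 + 0.85 (n - 3)`; exact interpolation remains
available by passing `lambda = 0` explicitly.  Duplicate coordinates are
perturbed by a seeded jitter of 1e-6 km.  Retention decisions evaluate the
spline at each sample's exact coordinates; the 200 x 200 export grid is
for plotting only.

## Spatial thinning

Heterogeneous sampling intensity distorts spatial genetic analyses, so the
sample is first homogenized: locations are clustered agglomeratively
(Lance-Williams updates; complete linkage by default) and the tree is cut
so clusters are separated by more than `cut_km` (default 50 km, twice a
typical seasonal movement distance for the motivating system), then at
most `max_per_cluster` (default 10) individuals are kept per cluster,
subsampled uniformly with a seed.  Individuals are ordered by (x, y, id)
before clustering so the partition does not depend on input order.

## Diversity and divergence statistics

Per group, `diversity_summary()` reports sample size, mean alleles per
locus (A), effective alleles (`Ae = 1 / sum(p^2)`), alleles at >= 5%
frequency (A95), observed and expected heterozygosity, and
`FIS = 1 - Ho/He` computed from the locus-averaged Ho and He.  He is plain
gene diversity `1 - sum(p^2)` (an unbiased variant is available behind a
flag) because the FIS identity is defined on that scale.  Frequency-based
statistics use pairwise-complete deletion per locus; loci with no data in
a group are excluded and flagged.

Divergence uses the two standard complementary estimators.  The
variance-components FST estimator (theta) computes the among-group (a),
among-individual (b) and within-individual (c) components per allele and
locus, and the multilocus estimate is `sum(a) / sum(a+b+c)`; small negative
values are a known property of the estimator and are not clipped.  Jost's
D uses unbiased within- and total-heterozygosity with the harmonic mean
group size; per-locus D is clipped to [0, 1], loci monomorphic across
groups are excluded, and the multilocus value is the arithmetic mean over
the remaining loci (source programs differ here; the mean is the simplest
defensible choice and is documented).  Both estimators are verified
against independently coded oracles to 1e-10 and at their exact limits
(fixation gives 1; identical groups give theta <= 0 and D = 0).

Hardy-Weinberg proportions are tested with a Monte-Carlo exact test:
observed alleles are shuffled into random diploid pairings, a simulated
table counts as extreme when its conditional probability is at or below
the observed table's, and `p = (extreme + 1) / (reps + 1)` so p is never
zero.  Gametic disequilibrium between loci uses a likelihood-ratio (G^2)
statistic on the genotype-by-genotype table with one locus permuted among
individuals.  Both are calibrated: under their nulls the p-values are
approximately uniform (checked by KS tests in the suite), and the HWP
Monte-Carlo p matches exact enumeration on a small worked case.
Family-wise wrappers apply Bonferroni across the whole (group x locus) or
(group x locus-pair) family.

Individual pairwise genetic distance is the codominant AMOVA squared
distance — per locus, half the squared Euclidean distance between
allele-count vectors (identical genotypes 0; opposite homozygotes 4) —
summed over loci typed in both individuals and rescaled by `L / L_typed`.

The Mantel correlogram splits geographic distance into equal-width classes
(80 by default) and correlates the genetic-distance matrix with each
class's model matrix, using the sign convention in which positive r means
genetic similarity within the class.  Significance comes from permuting
individual labels (two-sided on |r|), with progressive Bonferroni
correction (class k corrected for k tests).  By default classes are tested
only up to the class containing the largest nearest-neighbor distance,
which operationalizes "classes that include all points": beyond it, some
individuals contribute no pairs.  The per-class statistic is verified
against `vegan::mantel` on the identical model matrix.

## KDE center polygons

The complementary, one-shot view assigns each individual to its
maximum-membership cluster (ties toward the lowest index, flagged) and
draws utilization-distribution polygons per group: a bivariate normal
kernel with the reference bandwidth `h = sigma n^(-1/6)`,
`sigma = sqrt((var(x) + var(y))/2)`, on a 200 x 200 grid with a 10% (and
at least three bandwidths) margin.  The v-level contour encloses the
smallest-area region holding fraction v of the grid-normalized density
mass, so the 25/50/75% regions nest by construction; attained mass is
within grid resolution (2%) of nominal.  Groups below 5 individuals or
with zero spatial spread are rejected with advice rather than contoured.

## The simulators

Two generators produce the two regimes the methods must handle; all
randomness flows from the seed and identical configurations are
byte-identical.

**Hierarchical drift** (`simulate_hierarchical`): ancestral allele
frequencies per locus are symmetric-Dirichlet; each branch of a balanced
binary tree draws child frequencies from the Balding-Nichols construction
`Dirichlet(p (1-F)/F)`; genotypes are Hardy-Weinberg within terminal
demes.  Defaults emulate the motivating study's regime at desk scale: two
nested splits with F = 0.2 per branch (strong, drift-dominated structure of
small fragmented populations), 50 individuals per deme, 15 microsatellite
loci with 10 ancestral alleles.  Demes are placed so spatial nesting
matches genetic nesting (level-1 split along x, level-2 along y, offsets
halving per level; 400 km between the level-1 group centers, 25 km
individual scatter), and individuals are clumped into 5 unevenly used
"leks" per deme to reproduce clustered breeding-site sampling.
`n_levels = 0` gives a panmictic control.

**Stepping stone** (`simulate_stepping_stone`): forward-time Wright-Fisher
demes on a lattice (10 x 2 by default) with nearest-neighbor migration
(m = 0.01), symmetric stepwise mutation on a bounded 30-allele ladder
(steps past an end stay put), founded from a common pool concentrated on
the central third of the ladder.  Defaults run 1000 generations at deme
size 100 and mutation 2e-4: long enough that the dispersal scale
`sqrt(2 m T)` spans the lattice, giving pairwise divergence that grows
with lattice separation, while the sampled correlogram shows the
IBD signature of interest — significant similarity only at short range and
a non-significant mid-range transition.  Ten individuals are sampled per
deme at 50 km spacing with 5 km scatter.

What the simulators deliberately do not emulate: admixture zones with
continuous clines inside demes, linked loci, genotyping error and allelic
dropout, and the adaptive (non-random) field sampling of real surveys.
Passing the recovery tests therefore demonstrates correctness of the
machinery under the stated models, not robustness to every property of
real survey data.

## Problem sizes and numerical choices

The validation suite runs at desk scale, chosen to finish in minutes while
keeping each property measurable: parameter recovery on 4 demes x 50
individuals x 15 loci; the panmixia null at 200 individuals; estimator
oracles on 50 random small instances at 1e-10; permutation-test
calibration over 200 simulated datasets (KS at alpha = 0.01); correlogram
false-positive control over 100 seeded null datasets; the IBD signature on
the default lattice.  Other fixed numerical choices: permutation p-values
always use the `(+1)/(+1)` convention; EM convergence at 1e-6 on the
penalized objective; alignment exhaustive up to 5000 joint permutations
and 1000 greedy restarts beyond; membership surfaces clipped to [0, 1]
after evaluation; kriging GCV bounded at 85% of the available degrees of
freedom; exact-threshold samples (surface value equal to 0.70) are
retained.

## Known limitations

* Memberships are cross-fitted ML point estimates, not posterior means;
  cross-fitting trades some sharpness of genuine memberships (held-out
  information is half the loci) for calibration under no structure.  With
  few loci (< 6) the held-out information becomes thin and retention of
  genuine groups can weaken.
* The bifurcation tests splits by thresholding, not by significance; the
  package deliberately provides no p-value for "is this split real"
  (out of scope), so centers should be read together with G, the
  divergence matrix, and the correlogram.
* The thin-plate spline is isotropic and unbounded by barriers;
  anisotropy and landscape resistance are out of scope.
* Jost's D multilocus averaging and the He estimator follow the documented
  conventions above; other programs make different choices and small
  numerical differences against them are expected.
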