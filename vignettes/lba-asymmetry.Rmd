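---
title: "Topology-dependent long-branch attraction under site-heterogeneous models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-dependent long-branch attraction under site-heterogeneous models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lbazone)
```

## The question

Two of the hardest problems in animal phylogenetics — whether Ctenophora
or Porifera is the sister group of all other animals, and whether
Xenacoelomorpha is the sister of all other Bilateria (Nephrozoa) or of
the Ambulacraria (Xenambulacraria) — share a structure: one resolution
places two long branches (a fast-evolving clade and the outgroup) next
to each other, the other separates them by short internal branches.
Long-branch attraction (LBA) is the systematic error that joins long
branches because convergent substitutions are mistaken for shared
ancestry, and it is aggravated when the substitution model ignores
across-site heterogeneity in amino-acid frequencies: sparse site
profiles make convergence far more likely than a homogeneous model
expects.

The two arrangements are not symmetric targets of this error. When the
long branches are truly sisters (the *Farris zone*, or inverse
Felsenstein zone), LBA reinforces the true tree and inflates its
support. When they are truly apart (the *Felsenstein zone*), LBA pulls
inference toward the wrong, long-branches-together tree. `lbazone`
packages the simulation–inference machinery needed to demonstrate and
measure this asymmetry at desk scale: sequence simulation under
site-heterogeneous profile mixtures, pruning likelihoods and
branch-length optimization under matched and misspecified models,
candidate-topology evaluation with bootstrap split support, and the
surrounding experiments (branch-length bias, composite-data titration,
gene-quality ranking, taxon removal, cross-validation).

## Models

All models are reversible 20-state amino-acid substitution processes
built from an exchangeability matrix $S$ (the published LG values, or
Poisson/F81 equal exchangeabilities) and stationary frequency profiles
$\pi$, with $Q_{ij} = S_{ij}\pi_j$, rows summing to zero, normalized to
one expected substitution per unit branch length at stationarity.
Across-site rate variation is the standard discrete-gamma model:
$k$ equal-probability categories (default $k = 4$), each represented by
its category mean, unit mean overall; the shape $\alpha$ is a free
parameter (generator default 0.8, i.e. substantial rate variation).

Frequency heterogeneity across sites is a finite profile mixture: $m$
profiles $\pi^{(1)},\dots,\pi^{(m)}$ with weights $w$. The likelihood
of a site is the weighted sum over profiles and rate categories of the
Felsenstein pruning likelihood with that profile's $Q$ and the
category's rate multiplier; a single-profile model is exactly a
one-component mixture, and the code treats it so. This is the C-series
(C10/C60) construction; the Dirichlet-process CAT model is out of
scope, and where an empirical study would estimate CAT posteriors we
use a fixed profile set throughout. Two forms of adaptivity that real
C-series usage has are provided: the `plus_f` option appends the
alignment's observed frequencies as an extra component at fit time
(the "+F" class), and `optimize_mixture_weights()` re-estimates the
mixture weights by EM at fixed component likelihoods, pruning
components whose weight collapses — on compositionally homogeneous
data a "+F"-augmented mixture thereby reduces to its empirical class,
which is what makes heterogeneous-model branch lengths accurate on
homogeneous data (and keeps the optimizer's memory bounded, since
per-class conditionals are stored for every site). The recovery,
titration and cross-validation experiments keep weights fixed uniform,
matching the generating model. The
posterior mean site frequency (PMSF) approximation is implemented as in
its two-pass protocol: fit a homogeneous model, use that tree as a
guide to compute per-site posterior-weighted average profiles, then
analyse under the resulting per-site-profile model.

Gaps and unknown residues are treated as fully missing (a conditional
vector of ones), so an all-gap column contributes zero log-likelihood.

## Numerical implementation

The pruning core (C++ via Rcpp/RcppArmadillo) works from the symmetric
eigendecomposition of each $Q$, so $P(t) = V e^{\Lambda t} W$ and the
per-branch optimization objective can be written as
$\sum_k e^{\lambda_k t}\,(V^{\top}A)_k (W L)_k$ per site, where $A$ and
$L$ are the conditional likelihoods on the two sides of the branch.
After a one-off setup per branch, each line-search evaluation is a
single matrix–vector product. Branch lengths are optimized
coordinate-wise with Brent line searches on $[10^{-8}, 20]$
substitutions/site, sweeping the tree in preorder while partial
likelihoods are updated incrementally, so every objective is exact
under the current parameter values and the total log-likelihood is
non-decreasing across sweeps. Convergence is declared when a full sweep
improves the log-likelihood by less than `tol`; non-convergence within
`max_cycles` is flagged on the result rather than raised. Branches
whose length changed by less than 0.3% in the previous sweep skip their
line search (they are re-probed every fourth sweep) — a pure
coordinate-descent economy that does not change the optimum.
Conditional likelihoods are rescaled per node and per site with
accumulated log factors; without this, 20-state trees a few
substitutions deep underflow. Ties in candidate evaluation break by
candidate order, making every experiment deterministic under its seed.

The gamma shape is fitted by one-dimensional likelihood search on
$\log\alpha \in [\log 0.05, \log 10]$ at fixed branch lengths,
optionally alternated with branch-length sweeps. Mixture weights are
fixed (uniform by default); an EM-style re-weighting is deliberately
not part of the default fits since the experiments compare models with
matched weight handling.

## The synthetic study system

`make_backbone()` builds a 12-taxon tree of four three-taxon clades: an
outgroup and a focal clade with long terminal branches, and two
ingroup clades with short ones. The `farris` arrangement attaches the
focal clade next to the outgroup (long branches adjacent); the
`felsenstein` arrangement attaches it to the second ingroup clade,
separated from the outgroup by short internals. The two trees share an
identical multiset of branch lengths — only the attachment differs — so
any recovery asymmetry between them cannot be a tree-length artifact.

The default branch lengths are calibration knobs chosen once so the
system sits squarely in the LBA-sensitive regime, and they are not
estimates of any empirical dataset: outgroup terminals 2.0, focal
terminals 1.7/1.7/0.55, ingroup terminals 0.2, internal branches 0.07
substitutions/site. Two features matter. First, the flip of the
Felsenstein arrangement under a homogeneous model is driven by the long
terminals; at substantially shorter long branches (e.g. terminals near
1.0–1.2) the misspecification is real but too weak to change the
winning topology at these taxon counts. Second, each long clade
contains one slow tip (the "xenoturbellid analog" in the focal clade,
and a 0.8-length outgroup member would play the same role if
configured); true synapomorphies on the internal branches survive to
observable tips mainly through slow terminals, which is what keeps the
*correct*-model analysis of Farris-zone data decisive. The two fast
focal tips are recorded as the removable "acoelomorph analog" for the
taxon-removal experiment.

Profile heterogeneity is emulated by Dirichlet draws:
`make_profile_set(20, 0.2)` gives 20 sparse profiles (concentration 0.2
spreads most mass over a few amino acids per profile), uniform weights.
Sparsity is the feature that drives convergent substitutions; empirical
CAT posterior profiles are qualitatively similar in this respect.
Heterogeneous *inference* uses the same fixed profile set — matched
profiles, analogous to using C60 as a stand-in for CAT posteriors —
because estimating profiles from data is out of scope.

The gene-set generator grades quality the way empirical monophyly
ranking describes it: gene $g$ scales the backbone's terminal branches
by a factor running 0.5→2.0 across genes and the internal branches by
1.5→0.5, so best-end genes have short terminals and long internals
(the anti-LBA regime) and each gene carries its true rank for
validating rank recovery.

Replicate ensembles emulate simulating from distinct posterior samples
by perturbing every branch length with independent lognormal jitter
(sd 0.05 in log space) per parameter set; each replicate derives its
RNG stream deterministically from the run seed and replicate index.

## What the experiments show (and at what scale)

All headline experiments run at desk scale: 2,000-site alignments,
12 taxa, tens of replicates. With the defaults above:

- **Branch-length bias.** On heterogeneous data (4,000 sites) the
  homogeneous model estimates shorter lengths than the matched mixture
  on at least 90% of branches, with the relative shortfall largest for
  the longest branches; on homogeneous data both model classes recover
  the truth (mean absolute relative error under 10% at 20,000 sites,
  the mixture via "+F" EM weighting as above).
- **Asymmetry.** Farris-zone simulations are recovered by the
  homogeneous model in every replicate with essentially unanimous
  bootstrap support — misspecification *reinforces* the true tree.
  Felsenstein-zone simulations flip to the long-branches-sister tree in
  the large majority of replicates under the homogeneous model while
  the matched mixture recovers the truth.
- **Margins, not just winners.** Under the matched mixture, Farris-zone
  data yield small true-tree margins (a few to a few tens of log-units
  at 2,000 sites) because synapomorphies must survive ~2
  substitutions/site of terminal branch; the same data give the
  homogeneous model margins an order of magnitude larger. That
  inflation *is* the artifact. A consequence worth stating plainly: at
  2,000 sites an occasional near-tie under the correct model is
  expected by sampling noise, so "100% of replicates" statements about
  correct-model recovery become safe only at larger sequence lengths
  (margins scale linearly with sites; at the 30,000 sites of a typical
  phylogenomic subsample they are ~15-fold larger).
- **Titration.** Composites mixing Felsenstein- and Farris-simulated
  sites show a winner rate monotone in the mixing proportion; under the
  homogeneous model the crossover sits far above 50% Felsenstein
  content — balanced data support the Farris-zone tree.
- **Gene quality.** Monophyly-score ranking of the graded gene set
  recovers the built-in quality gradient (Spearman correlation > 0.6 at
  20 genes x 500 sites), and best-regime generation is easier to
  recover than worst-regime generation for both model classes.
- **Taxon removal.** Dropping the two fast focal tips raises
  homogeneous-model recovery of the Felsenstein-zone tree sharply, the
  classic empirical remedy.
- **Cross-validation.** On heterogeneous data the mixture model wins
  the held-out test log-likelihood in every repetition by large margins.

The test suite asserts exactly these statements at the sizes given; the
numbered scripts under `analysis/` run the same experiments as a
narrative workflow writing TSV tables under `results/`.

## What passing these tests does not show

The generator draws i.i.d. site profiles (no spatial autocorrelation
along the alignment), simulates no indels (gap handling is exercised by
unit tests, not by the generator), and holds exchangeabilities fixed
and branch-homogeneous. Real phylogenomic data additionally contain
heterotachy, compositional drift across lineages, alignment error and
contamination; a matched-mixture success here therefore does not imply
that any finite mixture suffices on real data — only that *unmodelled*
frequency heterogeneity of the kind simulated is enough by itself to
produce the topology-dependent artifact. The CAT-style
Dirichlet-process machinery, MPI-scale search, and ultrafast-bootstrap
internals are deliberately absent; the bootstrap here is the plain
nonparametric site-resampling bootstrap, computed exactly by
multinomial reweighting of per-site log-likelihoods when branch lengths
are held at their full-data estimates.

## Degenerate inputs and tie-breaks

Identical sequences drive branch estimates to the lower bound
($10^{-8}$); all-gap columns contribute likelihood 1; zero-length
generating branches produce ~50/50 bootstrap support between the two
resolutions; multifurcating input trees are rejected unless explicitly
resolved with zero-length branches; candidate ties go to the first
candidate by input order. Profiles with zero entries are clamped to
$10^{-10}$ and renormalized before rate-matrix construction.
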