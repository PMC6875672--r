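---
title: "Methods: co-occurrence network topology as a watershed bioassessment signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence network topology as a watershed bioassessment signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamnet)
```

## The problem

Stream bioassessment indices such as the California Stream Condition Index
(CSCI) score the biotic integrity of a *single* benthic macroinvertebrate
(BMI) sample against a reference expectation. Watersheds, however, are the
scale at which land-use stress operates and at which management decisions
are made. `streamnet` implements a watershed-scale assessment: groups of
samples drawn from one watershed (within narrow land-use and altitude
strata) are summarized as a genus co-occurrence network, and the topology of
that network is used to model the group's mean CSCI.

The pipeline has four stages:

1. **Stratified group selection.** Watersheds with at least 15 unique
   samples are kept; developed land use and altitude are each cut into
   global quintiles; within every watershed x land-use-quintile x
   altitude-quintile cell holding at least `g = 10` samples, `g` samples are
   drawn without replacement, and the draw is repeated `n_repeats` times.
2. **Null-model networks.** Per group, the presence/absence site x genus
   matrix is compared against `R = 100` randomized communities that preserve
   each site's genus richness exactly (taxa resampled uniformly from the
   group's genus pool). Each genus pair is scored as a standardized effect
   size, `ses = (obs - null mean) / null SD`; one-sided p-values come from
   the normal approximation to the SES, and positive associations passing
   both `p < 1e-4` and a Benjamini-Hochberg false-discovery threshold of
   `1e-4` become edges.
3. **Topology.** Per network: size `N` (genera present, isolated nodes
   included), connectance `C = 2E/(N(N-1))`, mean co-occurrence strength `S`
   (mean edge SES), modularity `M` (greedy agglomerative maximization,
   unweighted), and degree heterogeneity `zeta = <k^2>/<k>^2`.
4. **Index models.** Mean CSCI per group is regressed on the five topology
   measures with AIC backward elimination, repeated 10-fold cross-validation
   (100 repeats) and exact LMG relative-importance decomposition; a second
   model omits `N` to isolate the contribution of network *arrangement* from
   that of raw richness.

## Numerical and design choices

**Co-occurrence statistic.** The pairwise statistic is the joint-occurrence
count (sites where both genera occur), the classic quantity scored against
richness-preserving null communities. A Pearson-correlation alternative is
selectable (`pipeline_config(statistic = "pearson")`), but it cannot be
recommended at the default thresholds: a correlation is bounded at 1 while
its null SD over 10 sites is about `1/sqrt(10)`, so its SES can never reach
the value (about 4.8) that `p < 1e-4` demands -- with 10-sample groups the
Pearson variant retains essentially no edges, whatever the data. The SES
standardization removes the joint count's scale, so downstream metrics do
not depend on the raw statistic's units.

**Why normal-approximation p-values.** With `R = 100` null replicates an
empirical rank can never resolve probabilities near `1e-4` (the smallest
achievable rank-based p is about `1/101`), so p-values must come from the
standard-normal approximation to the SES. Calibration on structure-free
communities (i.i.d. occurrences) is checked in the test suite: pooled SES
has mean within 0.1 of zero and SD within [0.8, 1.25], and the fraction of
pairs passing the edge filter stays at or below 1e-3.

**False-discovery scope.** The Benjamini-Hochberg family is, by default,
*all candidate pairs of a run* pooled across its networks
(`pipeline_config(fdr_scope = "run")`), with a per-network family available
as `fdr_scope = "network"`. The run-wide family is the analysis-level claim
("which of all scored pairs are credible co-occurrences") and, numerically,
it applies one common SES threshold to every network. A per-network family
ties the threshold to the network's own candidate count, i.e. to `N^2`:
small (stressed) networks then pass edges at systematically lower SES than
large ones, which injects a spurious network-size artifact into the mean
edge strength `S` -- strong enough in simulation to cancel or even invert
the ecological trend in `S` along the stress gradient. The run-wide family
removes that artifact; both scopes leave `N`, `C` and the modularity
comparison essentially unchanged.

**Null counterpart networks.** Each observed network is paired with the
network obtained by treating the first replicate of its own null ensemble
as the observed community and pushing it through the identical scoring and
filtering. Under a correct null these counterparts retain edges only at the
false-discovery rate, so most are empty or nearly so; the paired
signed-rank comparison of modularity uses the pairs where both sides have
at least one edge.

**Missing-value policy.** Networks with `E = 0` have undefined `S`, `M` and
`zeta`; they are counted in the run manifest and excluded from model
fitting. `N < 2` leaves connectance undefined. Degenerate inputs (constant
land use, empty watersheds after filtering, cells smaller than `g`) warn or
skip rather than error, and the pipeline exits cleanly with empty tables.

**Determinism.** Every random draw (landscape, occurrences, group draws,
null ensembles, CV folds) uses a named substream derived by hashing
`(seed, stream label)`, so any single group or ensemble can be reproduced
in isolation and the whole run is reproducible from `(config, seed)`.

**Modularity.** Computed on the unweighted graph by fast-greedy
agglomeration; the exhaustive-search optimum over all partitions of up to
8 nodes is used as an oracle in the test suite. Greedy agglomeration is a
heuristic: on arbitrary graphs it can fall short of the optimum (the suite
asserts it never exceeds it), while on the suite's fixture set it attains
it exactly.

## What the synthetic generator emulates

`generator_config()` describes a California-like study system and the
defaults are the package's study conditions:

- **Landscape.** 56 watersheds x 25 sites (1,400 samples), watershed mean
  land use drawn from a right-skewed Beta distribution (most watersheds
  lightly developed), altitude 100-2,500 m, site-level noise of 6% land use
  and 150 m altitude within watersheds.
- **Taxon pool.** 334 genera in eight functional feeding groups; gatherers,
  filterers and omnivores form the generalist guild (47% of genera),
  scrapers and shredders the specialist guild (26%). Baseline prevalences
  are logit-normal (SD 1.6), giving a long tail of rare genera under a band
  of widespread ones; intercepts are calibrated so a site at the gradient
  centre holds about 30 genera in expectation.
- **Stress responses.** Occurrence log-odds change with standardized land
  use through (i) guild slopes (+0.25 generalist, -1.1 specialist, -0.35
  other), (ii) a community-wide richness decline (-0.4), and (iii) an
  occupancy-tolerance coupling (+0.6 per SD of baseline log-odds):
  widespread taxa tolerate or increase with development while rare taxa are
  lost first. The coupling is what lets connectance rise under stress --
  the rare tail (which inflates network size) collapses faster than the
  widespread, densely co-occurring core.
- **Co-occurrence.** Five latent niche axes with guild-clustered loadings
  (generalists on two broad axes, specialists partitioning the rest,
  loading 2.5); 20% of the axis variance is shared within a watershed.
  Aligned loadings generate genuine positive co-occurrence and modular
  network structure; setting the loadings to zero yields independent
  occurrences and, downstream, essentially edgeless networks.
- **Index.** `csci = 0.5 - 0.2 z(landuse) + 0.5 richness/target + N(0,
  0.08)`, independent of altitude by construction, mimicking an index
  designed to track stress while being robust to natural gradients.

The generator does *not* emulate temporal revisits of sites, spatial
autocorrelation beyond the watershed level, dispersal limitation along the
stream network, abundance structure (the pipeline is presence/absence
throughout), or taxonomic misidentification. Passing tests on synthetic
data therefore demonstrate that the pipeline recovers known stress effects
of this generative family; they do not validate the ecological claims on
any particular real dataset.

## Problem sizes used in tests and the acceptance script

The packaged analyses run the default landscape (1,400 sites) with ten
group draws per stratification cell, yielding roughly 600 networks of
10 sites each with 100-replicate null ensembles -- the scale at which the
stress-gradient sign structure, and in particular the paired
observed-versus-null modularity comparison (whose informative pairs arise
only where a null counterpart has edges), is statistically resolvable while
a full run completes in about a minute on one CPU. The cross-validation inside these
runs uses 10 folds with 10-20 repeats; the full 100-repeat setting is the
default for user analyses.

## Known limitations

- Groups drawn in different replicates from the same cell overlap in
  membership, and all replicate groups enter the model-fitting table: the
  pooled rows are pseudo-replicated, exactly as in the watershed analyses
  this package operationalizes. Standard errors and F statistics of the
  index models are conditional on that pooling and should not be read as
  independent-sample inference.
- With 10-site groups the joint-count SES is coarse; edge retention at
  `alpha = 1e-4` requires strong, consistent co-occurrence, and the mean
  strength `S` of sparse networks is dominated by values just above the
  retention threshold.
- The null model preserves site richness but not genus totals
  (equiprobable sampling from the group pool); a fixed-fixed algorithm
  would test a stricter hypothesis and is intentionally out of scope,
  though the scoring interface accepts any ensemble generator.
- Greedy modularity is a heuristic and the degree-heterogeneity of sparse
  networks with many isolated genera is large and heavy-tailed; comparisons
  of `zeta` across pipelines with different edge densities are not
  meaningful.
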