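# streamnet

Watershed-scale stream bioassessment from taxon co-occurrence network
topology.

Bioassessment indices such as the California Stream Condition Index (CSCI)
score the biotic integrity of one benthic macroinvertebrate (BMI) sample at
a time. `streamnet` asks what groups of samples say about a whole
watershed: it draws stratified groups of samples within watersheds, builds
a genus co-occurrence network per group against a richness-preserving
permutation null model, measures five topology metrics per network, and
models the group's mean CSCI from those metrics. It is aimed at stream
ecologists and bioassessment programs who have presence/absence BMI data
with land-use covariates, and at methodologists studying co-occurrence
networks under environmental stress.

## The method

For a group of `g = 10` samples from one watershed cell (joint land-use and
altitude quintile), the presence/absence site-by-genus matrix `X` is
compared against `R = 100` null communities that preserve each site's genus
richness exactly, taxa drawn uniformly from the group's genus pool. Each
genus pair `(i, j)` is scored by its joint-occurrence count and
standardized against the ensemble:

    ses_ij = (obs_ij - mean_null(ij)) / sd_null(ij)

One-sided p-values come from the standard-normal approximation to the SES;
positive associations with `p < 1e-4` and Benjamini-Hochberg `q < 1e-4`
(family: all candidate pairs of the run) become edges. Per network the
package reports

* size `N` (genera present; isolated nodes count),
* connectance `C = 2E / (N(N-1))`,
* mean co-occurrence strength `S` (mean edge SES),
* modularity `M` (greedy agglomerative maximization, unweighted),
* degree heterogeneity `zeta = <k^2> / <k>^2` (1 for regular graphs).

Mean CSCI per group is then modeled as a linear function of `(N, C, S, M,
zeta)` with AIC backward elimination, repeated 10-fold cross-validation and
exact LMG relative-importance decomposition (the average R-squared
contribution of each predictor over all orders of model entry).

A watershed-structured community simulator with known stress effects
(`generator_config()`, `simulate_bmi_dataset()`) makes the whole pipeline
testable end to end: richness declines with developed land use, specialists
drop out while widespread generalists persist, and latent niche axes induce
genuine co-occurrence structure.

## Worked example

Simulate the default study system (56 watersheds x 25 sites, 334 genera)
and run the pipeline with two group draws per stratification cell:

```r
library(streamnet)

cfg <- pipeline_config(n_repeats = 2, cv_repeats = 10, seed = 42)
res <- run_pipeline(cfg)
res
#> <pipeline_result>
#>   samples: 1400 in 56 watersheds (after filter)
#>   groups: 114, networks: 114 (0 without edges)
#>   index model: CV-R^2 = 0.900 (full), 0.313 (no size)
```

Network size falls along the land-use gradient:

```r
pearson_screen(res$topology$n_taxa, res$topology$mean_landuse_pct)
#> # A tibble: 1 × 3
#>        r  p_value     n
#>    <dbl>    <dbl> <int>
#> 1 -0.627 8.52e-14   114
```

The index model and its relative-importance decomposition (here the AIC
elimination dropped modularity; with more group draws all five measures are
typically retained):

```r
glance(res$model_full)
#> # A tibble: 1 × 4
#>       n r_squared cv_r_squared   aic
#>   <int>     <dbl>        <dbl> <dbl>
#> 1   114     0.909        0.900 -232.

tidy(res$model_full)[, c("term", "estimate", "f_statistic",
                         "importance_pct_explained")]
#> # A tibble: 5 × 4
#>   term                 estimate f_statistic importance_pct_explained
#>   <chr>                   <dbl>       <dbl>                    <dbl>
#> 1 (Intercept)           0.823         NA                       NA
#> 2 connectance          -5.95           9.27                    12.0
#> 3 degree_heterogeneity -0.00190        3.71                     2.10
#> 4 mean_strength        -0.0950        23.3                     11.5
#> 5 n_taxa                0.00553      654.                      74.4
```

Cross-validated R-squared of 0.90 against 0.31 for the size-free model says
most — but not all — of the watershed signal is carried by network size
(taxon richness); connectance and co-occurrence strength add information
about how the surviving community is arranged.

`autoplot(res$model_full)` draws the fitted-versus-observed mean CSCI
scatter colored by land use; `plot_topology_trends(res$topology)` shows
each topology measure along the gradient. Real data enter through
`run_pipeline(cfg, samples = "samples.csv", occurrences = "occurrences.csv",
taxa = "taxa.csv")`; see `?read_samples` for the schemas. A thin CLI wrapper
lives at `inst/cli/streamnet.R`.

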