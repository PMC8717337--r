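# phylocomgrad

Community phylogenetics along environmental gradients, for presence–absence
inventory data. The package targets the common study design in tropical plant
ecology where a set of inventory transects is distributed across an edaphic
gradient (here, soil exchangeable base cations: Ca + K + Mg + Na in
cmol(+)/kg, spanning three geological strata), each transect is scored for
species presences of one or more focal lineages, and phylogenetic community
structure is asked to reveal how the gradient filters lineages — e.g. whether
poor-soil communities are assembled from a few specialist clades
(phylogenetic clustering) while rich-soil communities sample the phylogeny
more evenly.

## What it computes

For a binary site × species matrix, a rooted dated phylogeny (or a posterior
sample of them), and a site environment table:

**Alpha (per site):** species richness *S*; Faith's PD (total branch length
of the minimal spanning subtree of the present taxa, *root-excluded*: no edge
above their MRCA); MPD = (2/S(S−1)) Σ_{i<j} d_ij, the mean pairwise
patristic distance; MNTD = (1/S) Σ_i min_{j≠i} d_ij, the mean nearest-taxon
distance; and VPD (Λ⁺) = Σ_{i<j} (d_ij − MPD)² / (S(S−1)/2), the variance of
pairwise distances. VPD is reported unstandardized; PD, MPD and MNTD are
standardized as SES = (observed − null mean)/null sd against an
**independent-swap** null (checkerboard 2×2 flips preserving every row and
column sum; 999 null communities per tree at study scale), computed
separately for each tree of the posterior sample and summarized across trees
by the median.

**Beta (per site pair):** Sørensen dissimilarity (b+c)/(2a+b+c) and PhyloSor,
the proportion of branch length not shared between the two communities'
subtrees (both measured to the MRCA of the pooled pair). SES.PhyloSor uses a
**tip-shuffle** null (tree labels permuted, community fixed; 100 trees × 10
shuffles = 1000 pooled null values at study scale), with site pairs tagged
within/between geological formation for stratified summaries.

**Gradient analysis:** PCoA of either beta matrix (Gower double-centering,
negative eigenvalues reported rather than corrected) with environmental
correlation arrows, and linear + second-order polynomial regressions of each
metric on log10 base-cation concentration with adjusted R² and F-test
p-values.

**Synthetic data:** a generator that emulates the stratified study design
(40 sites split 9/12/19 across the Solimões / Içá / terrace strata with
calibrated cation distributions) and assembles communities by Gaussian niche
filtering over phylogenetically structured edaphic optima, in four scenarios
(`fern_like`, `palm_like`, `clustered`, `neutral`) with the full truth record
kept, so every stage of the pipeline is testable offline.

## Worked example

```r
library(phylocomgrad)

ds <- generate_dataset("fern_like", seed = 42)   # 40 sites x 60 taxa, 10 trees
al <- align_dataset(ds$community, ds$env, ds$trees)

alpha <- alpha_over_trees(al$community, al$trees)
head(alpha, 4)
#>   site  S   PD   MPD  MNTD   VPD
#> 1  T01 20 2500 486.6 140.6 36990
#> 2  T02 21 2517 525.8 121.6 36768
#> 3  T03 22 2589 528.5 126.7 38883
#> 4  T04 17 2125 503.2 116.6 40997

sa <- ses_alpha(al$community, al$trees, metrics = c("MPD", "MNTD"),
                config = null_config(n_null_per_tree = 99, seed = 1))
head(sa$summary[sa$summary$metric == "MPD", ], 4)
#>   site metric observed null_mean null_sd   ses quantile n_trees n_null
#> 1  T01    MPD      487       556    14.8 -4.83   0.0000      10     99
#> 2  T02    MPD      526       556    13.5 -2.52   0.0202      10     99
#> 3  T03    MPD      528       554    13.6 -2.12   0.0354      10     99
#> 4  T04    MPD      503       554    17.2 -2.87   0.0101      10     99

reg <- fit_gradient_models(alpha[, c("site", "S", "VPD")], al$env)
reg[, c("metric", "linear_slope", "linear_adj_r2", "linear_p")]
#>   metric linear_slope linear_adj_r2 linear_p
#> 1      S         6.94         0.651 1.99e-10
#> 2    VPD     -5548.71         0.139 1.03e-02
```

The first four sites are Solimões (cation-rich) transects: their SES.MPD is
strongly negative — the species that co-occur there are closer relatives
than the independent-swap expectation. The regression table shows the
`fern_like` scenario's built-in signature: richness rises (slope +6.9 species
per decade of cation concentration, adjusted R² 0.65) while VPD falls along
the gradient.

The whole pipeline (alpha, SES, beta, ordination, regression, with
per-stage JSON run logs) runs from one call:

```r
run_pipeline(run_config(scenario = "fern_like", seed = 42), "runs/fern42")
```

or from the shell via `inst/scripts/run-pipeline.R`. Use
`paper_scale = TRUE` for study-scale null effort (100 trees × 999 swap
nulls); the default is the scaled-down 10 × 99 for interactive work.

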