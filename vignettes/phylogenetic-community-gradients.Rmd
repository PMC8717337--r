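---
title: "Phylogenetic community structure along an edaphic gradient: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic community structure along an edaphic gradient: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocomgrad)
```

## The question and the data model

Inventory transects distributed across an abrupt edaphic boundary — here a
soil base-cation gradient spanning three geological strata (cation-rich
clays vs. two kinds of cation-poor loams) — let us ask whether local plant
communities are phylogenetically structured by the gradient: do poor-soil
communities sample only the few lineages that tolerate poor soils
(clustering), and do rich-soil communities sample the phylogeny more evenly?

The package's data model has three aligned objects: a binary site × species
matrix (presence–absence only; abundance weighting is deliberately out of
scope), a site environment table (base-cation concentration in cmol(+)/kg,
strictly positive so `log10` is defined, plus a three-level formation
factor and optional P / Al / pH covariates), and a rooted, branch-length
dated phylogeny — usually an ordered sample of trees from a Bayesian
posterior, all over the same tip set, so that dating uncertainty propagates
into every downstream statistic. `align_dataset()` fixes one site and taxon
ordering for everything downstream and prunes the trees to the observed
taxa; the species pool for all null models is exactly the aligned matrix's
taxon set (all observed species of the focal lineage). Subclade analyses
are done by subsetting taxa and re-aligning before any null model runs.

## Metrics

With $d_{ij}$ the patristic distance between species $i$ and $j$ and $S$
the site's richness:

* **PD** (Faith): total branch length of the minimal subtree connecting the
  present taxa, rooted at their MRCA — *root-excluded*, i.e. no edge above
  the MRCA is counted. A single-taxon site has no defined subtree, so PD is
  missing (never 0) for $S < 2$; this propagates as explicit missingness.
* **MPD** $= \binom{S}{2}^{-1}\sum_{i<j} d_{ij}$ — dominated by deep
  divergences.
* **MNTD** $= S^{-1}\sum_i \min_{j \ne i} d_{ij}$ — emphasizes the tips.
* **VPD** ($\Lambda^+$) $= \binom{S}{2}^{-1}\sum_{i<j}(d_{ij}-\mathrm{MPD})^2$
  — the *population* variance over the multiset of pairwise distances
  (denominator = number of pairs, not pairs − 1), elevated when a community
  mixes very close and very distant relatives. VPD is insensitive to
  sampling effort and is therefore reported on the observed scale, never
  standardized; the pipeline deliberately emits no SES.VPD.
* **Sørensen** $(b+c)/(2a+b+c)$ and **PhyloSor**, its branch-length
  analogue: $1 - \mathrm{BL}_{shared} / \tfrac12(\mathrm{BL}_A +
  \mathrm{BL}_B)$.

PhyloSor's three PD terms are measured on subtrees rooted at the MRCA of
the *pooled pair* $A \cup B$. With per-set MRCA rooting the decomposition
$\mathrm{BL}_{shared} = \mathrm{BL}_A + \mathrm{BL}_B -
\mathrm{BL}_{A\cup B}$ is ill-defined (it can go negative); with pooled
rooting it is exact and non-negative. This deliberately differs from the
root-excluded convention used for Faith's PD in the alpha metrics: the two
conventions serve different statistics. Degenerate single-taxon sites are
permitted in PhyloSor (their BL is the tip-to-pooled-root path), and an
identical single-taxon pair is defined as dissimilarity 0 by continuity.

Internally, both PD and PhyloSor run on a tips × edges incidence matrix of
root paths: the edges spanned by a site are the union of its tips' root
paths, and the edges above a taxon set's MRCA are exactly those on *every*
root path. That turns per-site PD into two matrix products and all
$\binom{n}{2}$ PhyloSor values per tree into two weighted cross-products —
the identity that makes 1000-fold tip-shuffle nulls affordable.

## Null models and standardized effect sizes

Two nulls, used for different statistics:

* **Independent swap** (community null, for SES.PD/MPD/MNTD): repeatedly
  draw a random 2×2 submatrix and flip it iff it is a checkerboard. Every
  draw preserves each site's richness and each species' occupancy exactly.
  Swap effort counts *successful* swaps — 1000 per null matrix by default —
  with an attempt cap of 100 × (rows × cols) so mixing is comparable across
  matrix shapes and a checkerboard-free (e.g. perfectly nested) matrix
  terminates with a warning rather than spinning. Both knobs are in
  `null_config()` and recorded in run logs.
* **Tip shuffle** (phylogeny null, for SES.PhyloSor): permute the tip
  labels of the tree, keeping topology and branch lengths — and hence the
  full cophenetic distance multiset — fixed, while destroying any
  association between relatedness and co-occurrence.

SES $= (\text{obs} - \mu_{null})/\sigma_{null}$; negative values mean
closer relatives than expected (clustering), positive mean overdispersion.
Wherever $\sigma_{null} = 0$ (degenerate null, e.g. PhyloSor between two
identical communities, which is 0 under every relabelled tree) the SES is
reported missing rather than fabricated.

Aggregation over the posterior tree sample: for the alpha metrics, nulls
are generated independently for each tree (999 per tree at study scale) and
the per-site result is the cross-tree **median of the per-tree SES
values**. Whether the median should be taken over SES or over the raw
metric before standardization is ambiguous in the design this package
follows; the SES-median is the default because the standardized metric is
what enters the gradient regressions, and `summary = "mean"` plus the
per-tree arrays in the returned object cover the alternative reading. For
SES.PhyloSor the observed value is the cross-tree summary (default median)
of the per-tree PhyloSor, and the null distribution pools all trees ×
shuffles (100 × 10 = 1000 values per pair at study scale); the summary
statistic is likewise configurable. A `share_nulls` flag can reuse one
swap-null set across trees as a speed-up; the default regenerates per tree,
which is the faithful reading of the design.

Randomness is governed by one master seed per run: per-tree and per-stage
sub-seeds are derived by a fixed split (`sample.int` under the master
seed), so results are independent of evaluation order and byte-identical
across reruns.

## Ordination and gradient regressions

PCoA is the classical Gower construction: eigendecomposition of
$-\tfrac12 C D^2 C$. Negative eigenvalues — expected for Sørensen-type
dissimilarities — are reported, not corrected (no Cailliez/Lingoes by
default, the most common choice for this input), so their magnitude can be
judged. Axes are deterministically oriented so each axis's
largest-magnitude score is positive, making plots and tests reproducible.
Environmental arrows are Pearson correlations of each (transformed)
variable with the first two axes.

Regressions fit $y = b_0 + b_1 x$ and $y = b_0 + b_1 x + b_2 x^2$ with
$x = \log_{10}(\text{base cations})$ by default; a raw-scale predictor
option is retained because either reading of the display convention is
defensible. The quadratic is fit on centered $x$ for conditioning and
back-transformed to the raw polynomial basis. Model p-values come from the
F-test against the intercept-only model (default) or the highest-order
coefficient's t-test; significance flags use p < 0.05. Sites with missing
metric values are dropped per metric with a logged message — never
silently zero-filled — and a metric with fewer than 4 complete sites is
skipped.

## The synthetic generator

`generate_dataset()` emulates the study design so the full pipeline runs
and is testable with no external data:

* **Environment**: 40 sites split 9 / 12 / 19 across Solimões / Içá /
  terrace strata. Per-stratum cation concentrations are log-normal,
  calibrated by treating the design range as a central 95% interval of the
  log-normal (fixing `sdlog`) and then matching the arithmetic mean
  exactly in expectation (`meanlog = log(m) - sdlog^2/2`; design means
  7.59, 0.16, 0.37 cmol(+)/kg). The design ranges are not exactly
  symmetric around the means on the log scale, so range coverage is
  approximate while mean matching is exact. P, Al and pH are noisy
  monotone functions of the cation value — they exercise the ordination
  arrows but carry no independent truth.
* **Trees**: pure-birth (Yule) trees rescaled to an exact crown age (330
  Ma for the fern-like scenario, 106 Ma palm-like), chosen over
  birth–death for parsimony — tree-shape realism is not what these data
  test. A pseudo-posterior is made by multiplying every branch by
  independent mean-1 log-normal factors (default CV 0.1), topology fixed.
* **Niches and assembly**: each species gets an optimum $\mu$ on the
  log10-cation axis, tolerance $\tau$, and ceiling $p_{max}$; presence is
  an independent Bernoulli with
  $P = p_{max}\exp(-(x_j-\mu_s)^2/2\tau_s^2)$. Optima evolve either by
  Brownian motion (conserved niches, no bias) or by a biased two-state
  process: a poor/rich preference character with asymmetric rates
  ($q_{pr} \gg q_{rp}$ from a poor root yields a majority rich-adapted
  pool whose poor-soil specialists are concentrated in the few lineages
  that never left the poor state — the niche-shift-bias hypothesis), with
  $\mu$ drawn from state-conditional normals.

Scenario presets: `fern_like` (deep tree, strong poor→rich bias, narrow
$\tau = 0.35$, $p_{max} = 0.7$: specialists, richness rising with cations),
`palm_like` (young tree, symmetric slow rates from a poor root so most
species stay poor-adapted, broad $\tau = 0.7$, $p_{max} = 0.85$:
generalists, richness falling), `clustered` (one clade of about a quarter
of the tips exclusively poor-adapted: poor-soil communities are drawn from
a single clade, the cleanest clustering truth), and `neutral` (optima
independent of the phylogeny and uniform over the gradient, with
$\tau = 12$ — far broader than the ~2.3-decade gradient span — so expected
occupancy is flat across sites). The broad neutral tolerance matters: with
a tolerance comparable to the gradient, a finite species pool of
gradient-limited optima mechanically concentrates niche mass mid-gradient
and each realized pool carries a random richness trend, which would make
the "no effect built in" control fail its own definition. Scenario
parameters are design knobs recorded in the truth record, not estimates of
any real system.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: spatial autocorrelation along the river,
dispersal limitation, abundance structure, sequence-level dating
uncertainty beyond branch jitter, and correlated environmental covariates
with independent effects. Tests on these data validate the *machinery*
(metrics, nulls, calibration, recovery of built-in signals), not ecological
conclusions.

## Numerical and scale choices

* Distances are patristic (branch-length) distances in Ma, never node
  counts; nothing assumes ultrametricity (posterior draws need not be
  ultrametric after pruning).
* Zero-length branches are accepted; negative or missing lengths are
  errors at parse time (no silent zero-fill). Tip matching is exact and
  case-sensitive after trimming quotes/whitespace.
* Missing metric values (S < 2 sites, degenerate nulls) are explicit `NA`s
  that propagate to regression with logged drops.
* VPD clamps tiny negative floating-point residue of the
  $E[d^2]-E[d]^2$ form at 0.
* Default problem sizes are the scaled-down interactive settings — 60
  taxa, 40 sites, 10 trees × 99 swap nulls — chosen so a full pipeline run
  takes seconds; `paper_scale = TRUE` switches to 100 trees × 999 nulls.
  The test suite's calibration check runs 20 sites × 199 nulls × 200
  replicates; the oracle-equivalence check enumerates every taxon subset
  of 50 random trees of up to 8 tips.
* The hot loops (checkerboard swaps, per-null MPD/MNTD) are in C++ via
  Rcpp, drawing from R's RNG so `set.seed()` governs everything.

## Known limitations

Only the two nulls used by the analysis are implemented (no frequency- or
trial-swap variants, no abundance nulls); Sørensen is not decomposed into
turnover/nestedness components; ordination offers no NMDS/db-RDA; and the
independent swap, like all checkerboard samplers, mixes slowly on very
dense or very sparse matrices — the effort counters in the run log are the
tool for judging that.
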