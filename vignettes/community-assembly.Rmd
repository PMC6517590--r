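---
title: "Detecting deterministic and stochastic community assembly with phylodecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting deterministic and stochastic community assembly with phylodecay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodecay)
```

## The question and the model

A community time series — here, taxa detected in dated lake-sediment
layers across several lakes — can be assembled deterministically (the
environment filters which taxa establish) or stochastically (dispersal and
drift decide). The two leave different phylogenetic fingerprints when the
traits under selection are phylogenetically conserved:

* **Filtering** draws co-occurring taxa from the clades whose traits match
  the local environment, so communities are *phylogenetically clustered*
  relative to random draws from the species pool, and community
  dissimilarity grows along environmental gradients regardless of
  geography.
* **Dispersal limitation** makes composition depend on where propagules
  come from: communities decay in similarity with *geographic* distance,
  while their internal phylogenetic structure stays random.
* **Neutral assembly** predicts neither signal beyond type-I noise.

`phylodecay` tests all three fingerprints.

### Within-community structure: MNTD, SES and NTI

For a community of $n \ge 2$ taxa with patristic distances $d_{ij}$ (sum of
branch lengths on the tip-to-tip path),

$$\mathrm{MNTD} = \frac{1}{n}\sum_i \min_{j \ne i} d_{ij},$$

the mean distance to the nearest co-occurring relative — sensitive to the
tips of the phylogeny, where ecologically relevant divergence is most
recent. The null model permutes taxon labels across the tips of the
species-pool phylogeny, keeping richness and tree shape fixed; under it a
community's MNTD is distributed as the MNTD of a uniformly random
richness-$n$ subset of the pool. With `n_rand` draws (default 999, the
conventional count),

$$\mathrm{SES}_{\mathrm{MNTD}} =
  \frac{\mathrm{MNTD}_{obs} - \overline{\mathrm{MNTD}}_{null}}
       {\mathrm{sd}(\mathrm{MNTD}_{null})},
\qquad \mathrm{NTI} = -\mathrm{SES}_{\mathrm{MNTD}}.$$

Classification uses the empirical 2.5% / 97.5% quantiles of the null
draws — not a Gaussian $\pm 1.96$ cutoff on SES, although both numbers are
reported — because the null distribution of MNTD is skewed at moderate
richness. A community below the lower quantile is *clustered*, above the
upper *overdispersed*, otherwise *random*. MPD (the mean over all pairs,
sensitive to basal structure) runs through the same machinery behind
`metric = "mpd"`.

**Species pools change through time.** The pool for a sample is the union
of taxa observed in any sample of its decade, across all lakes
(`build_pools()`). This is a deliberate interpretation of a time-varying
regional pool: taxa that had not yet arrived in the region cannot appear in
a null community of that era. The binning granularity is configurable via
`bin_fun`.

Degenerate inputs are handled explicitly: a community that exhausts its
pool has a null with zero variance, so SES is reported `NA` and the
classification falls back to `"random"`; richness-1 communities are
rejected (and skipped with a warning in batch mode).

### Exhaustive mode and its SD convention

For small pools, `ses_phylo(..., exhaustive = TRUE)` enumerates all
$\binom{m}{n}$ equally likely subsets instead of sampling. Its null SD is
the *sample* SD over the $K$ enumerated values (denominator $K-1$); random
draws, by contrast, estimate the *population* SD of that distribution,
smaller by $\sqrt{(K-1)/K}$. The distinction is visible only for toy pools
(for $K = 6$ the factor is 0.913) and is accounted for explicitly where
the test suite compares the two modes; for realistic pools it is
negligible.

### Between-community structure and distance decay

Three beta-diversity metrics are computed over all sample pairs:
beta-MNTD (mean of each taxon's nearest cross-community distance, averaged
over the two directions), beta-MPD (mean over all cross pairs) and
UniFrac (fraction of branch length unique to one community, over branches
with any descendant in either; weighted variant optional). All default to
presence/absence, the conventional default of these metrics; abundance
weighting sits behind a flag because rarefied counts carry real but noisy
abundance information. beta-MPD of a sample with itself is nonzero by its
formula; the reported matrix forces the diagonal to zero and self-pairs
never enter any regression.

Decay statistics mirror standard practice:

* **Geographic.** Distance between lakes is great-circle (haversine,
  mean Earth radius 6371 km). Because repeated sampling of the same lakes
  through time would confound time with space, the geographic analysis
  uses same-decade pairs only, and the Mantel test runs separately within
  each decade (bins below `min_bin_samples` are excluded); the per-decade
  one-sided p-values are combined with Fisher's method. Same-lake pairs
  have distance 0, so the OLS predictor is $\ln(\mathrm{km} + 1)$, and
  `exclude_same_lake = TRUE` reruns the fit without them.
* **Temporal.** Within-lake pairs against $\ln(\mathrm{years} + 1)$.
* **Environmental.** One-dimensional Euclidean gradients
  $|\,v_i - v_j\,|$ of annual environmental values smoothed over a 3-year
  window centred on the layer's dated year (a buffer against dating
  uncertainty; configurable to trailing). Pairs missing a variable drop
  out of that gradient only. Following the logic that only non-random
  communities carry a deterministic signal, these regressions restrict to
  pairs whose *both* members are non-random (`pair_rule = "either"`
  relaxes this).

OLS on pairwise distances ignores the non-independence of pairs sharing a
sample — conventional for distance-decay plots — which is why the Mantel
companion (simultaneous row/column permutation, one-sided *greater*,
$p = (1 + \#\{r^\ast \ge r\})/(n_{perm}+1)$) is always emitted alongside.
Decay is a directional claim: a *negative* significant geographic slope is
not decay, so regime calls in the acceptance suite use one-sided positive
tests.

## The synthetic-data generator

`scenario_config()` + `simulate_bundle()` produce a complete study with
known ground truth. Defaults describe the study design the package was
built around — ten lakes in a peri-Alpine-sized region, layers spanning
1900–2016 (12 per lake), a 256-taxon regional pool — with these choices:

| Parameter | Default | Why |
|---|---|---|
| tree | Yule, unit birth rate | simplest null shape for an OTU phylogeny; ultrametric |
| traits | Brownian motion, $\sigma^2 = 1$ | phylogenetically conserved traits, the precondition for filtering to leave a clustering signal |
| pool growth | 40% of taxa in the first decade, linear to 100% | exercises the time-varying pool machinery |
| richness | Poisson, mean 50 (clipped to [5, pool]) | typical of rarefied amplicon assemblages; the tip-sensitive MNTD needs communities of this size for per-sample power |
| sequencing | depth $\sim$ logNormal(log 8000, 0.25), min 3000; multinomial reads | samples survive rarefaction to 2744 |
| warming | +0.01 °C/yr, +0.05 °C/yr after 1980, noise SD 0.3 °C | century-long warming that accelerates late, as in peri-Alpine monitoring |
| TP | 15 µg/L baseline + 90 µg/L Gaussian peak at 1975 (width 20 yr) | eutrophication then re-oligotrophication |
| SSI | 500 + 90 per °C anomaly | stratification strengthens with warming |
| NO3/NH4 | stationary noise (1 ± 0.15, 0.05 ± 0.01 mg/L) | nutrients without a secular trend |
| filtering | $w \propto e^{-(x - \mathrm{opt})^2 / 2\sigma_{niche}^2}$, $\sigma_{niche} = 0.25$ | strong filtering: communities are essentially the nearest-trait taxa; $\sigma_{niche}=0$ is the exact deterministic limit |
| optimum map | realized temperature range → central 5–95% trait range | lakes with different climates select distinct portions of the pool; the map is stored in the ground truth |
| dispersal | home lake per taxon, $w \propto e^{-d/25\,\mathrm{km}}$ | kernel well below inter-lake distances, i.e. marked limitation |

Weighted sampling without replacement uses the Gumbel top-$k$ construction
in log space, so steep niches cannot underflow when an optimum sits far
into one trait tail. Temperature baselines are assigned to lakes
independently of their coordinates, so the filtering regime does not
accidentally manufacture a geographic gradient.

**What the generator does not emulate:** sequence-level noise (chimeras,
OTU clustering artifacts), sediment taphonomy and DNA degradation,
abundance structure beyond uniform-multinomial within a community,
covarying environmental drivers (TP and temperature are independent here),
and trait evolution beyond single-trait Brownian motion. Passing tests
therefore demonstrate that the *statistical machinery* recovers known
regimes from idealised data; they do not certify robustness to the
taphonomic and bioinformatic quirks of real sedimentary DNA.

## Verification strategy and problem sizes

The test suite checks every metric against independent brute-force oracles
(naive path sums on the tree's edge graph, quadratic-loop metrics) to
1e-10 on 100 random trees, and against the reference implementations in
`picante` where definitions coincide (note `picante::comdistnt` pools the
two directional nearest-taxon vectors, which equals the
average-of-directional-means definition used here only at equal richness).
The null model is validated three ways: exact agreement with exhaustive
enumeration on a 4-tip reference tree (null mean $10/3$, NTI $+1.291$ for
the within-cherry pair), convergence of 999-draw estimates across 100
seeds, and type-I calibration — 200 neutral communities against a
256-taxon Yule pool classify non-random at a rate inside [0.02, 0.09].
Regime recovery runs the full pipeline on one default-sized bundle per
regime (120 samples, 999 randomisations and permutations): filtering must
show a positive temperature-gradient slope and no positive geographic
decay, dispersal limitation the reverse, neutral neither. Clustering
recovery under filtering is scored against the generator's known decade
pools, isolating the classifier from pool-estimation error; the same
analysis with observed-union pools yields a visibly lower flagged
fraction, a useful reminder that empirical pool construction absorbs part
of the signal. Determinism is asserted byte-for-byte on rerun pipelines.

These sizes — and the 999/999 randomisation defaults — are the package's
chosen verification conditions; all are plain arguments, so heavier
simulations are one call away.

## Known limitations

* The tip-shuffle null is the only null model (no independent-swap or
  frequency-preserving variants); it answers "are these taxa a random draw
  from the pool's phylogeny?", nothing finer.
* MNTD-based NTI has bounded power: a tight clade is *not* flagged when
  the pool contains other equally tight structure, and per-sample power
  grows with richness. MPD/NRI complements it at basal scales.
* OLS p-values on pairwise distances are anti-conservative under pair
  dependence; treat them as descriptive alongside the Mantel results.
* The decade-union pool is an interpretation of a time-varying regional
  pool, not an estimate of the true colonisable pool; rare taxa missing
  from a decade's samples shrink it.
* UniFrac is reported unweighted/weighted only — no generalized-UniFrac
  family, no Faith's PD.
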