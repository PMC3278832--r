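---
title: "Measuring monochromaticity: models, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring monochromaticity: models, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcindex)
```

## The model

A quantitative genetic interaction is the deviation of a double mutant's
fitness from the multiplicative expectation under its two single mutants,
`epsilon = phi_AB - phi_A * phi_B` (`epsilon_score()`). Only the sign and
magnitude of `epsilon`, and the associated p-value, enter any statistic in
this package; fitness values themselves are never stored. An interaction
with `epsilon = 0` carries no sign and is dropped at read time, because
every downstream statistic needs a binary sign.

Clusters are defined set-theoretically from a complex catalog: an
interaction is *within-complex* when both genes belong to the same complex,
and *between-complex* for a pair of distinct complexes when it has one gene
in each. Consensus complex catalogs overlap, so one interaction can
legitimately appear in several clusters; the `exclude_within` flag of
`build_between_clusters()` optionally removes complex-internal interactions
from all between-complex clusters (off by default, since either reading is
defensible and with disjoint complexes they coincide).

For a cluster with `N_pos` positive and `N_neg` negative interactions, the
signed purity is `beta = (N_pos - N_neg) / N`. The population-level
monochromatic index is the interaction-count-weighted mean of `|beta|`,

$$\mathrm{MCI} = \frac{\sum_i N_i\,|\beta_i|}{\sum_i N_i} \in [0, 1],$$

weighting by cluster size because clusters with more screened interactions
estimate their purity more reliably. Note the aggregation uses `|beta_i|`,
not signed values: the index must reach 1 for *pure positive or pure
negative* clusters alike and 0 only for balanced ones. The strength-based
variant replaces the count purity with the net-over-gross strength ratio
`|sum_j epsilon_j| / sum_j |epsilon_j|` per cluster, keeping the same
size weights. This per-cluster statistic was chosen because it lies in
`[0, 1]`, is invariant to rescaling all strengths, and reduces exactly to
`|beta|` when all magnitudes in a cluster are equal — an identity the test
suite verifies by brute force over random sign patterns. It is a
reconstruction: the historical definition of the strength-based index is
not recoverable in closed form from its published description, so the exact
functional form here is this package's own, documented choice.

## Significance

Two complementary routes are provided.

**Permutation null (`permutation_null()`).** Cluster contents are replaced
by interactions drawn at random from the screened pool while the cluster
size multiset stays fixed; the statistic is recomputed per replicate.
The default draw is one joint sample *without* replacement per replicate — a
true relabeling of interactions — because it preserves the pool's exact sign
composition in every replicate; independent per-cluster draws and
with-replacement sampling are available behind flags since the historical
procedure's sampling mode is not documented. Defaults: `b = 1000`
replicates and a fixed, recorded seed, so results are bit-reproducible.
The empirical p-value is the proportion of null values `>=` the observed
one (ties count against significance; an add-one `(r+1)/(b+1)` estimator is
available), reported as `< 1/b` when no replicate reaches the observed
value. The Z-score `(obs - mean)/sd` is reported alongside and flagged
undefined when the null variance is zero (e.g. a single-signed pool, where
every permutation is pure).

This construction is what makes the index background-aware: a heavily
sign-imbalanced pool drags the null MCI mean upward, so a high observed MCI
over a negative-dominated stringent screen earns a much smaller Z than the
same value over a balanced lenient screen. The test suite checks this
monotonicity directly.

**Exact binomial test (`binom_upper_tail()`).** For per-complex calling, the
number of monochromatic complexes among `n` under a sign-agnostic null is
`Bin(n, 1/2)`; significance is the exact upper tail from the observed count
`x` to `n`, computed via `stats::pbinom` (which works in log space
internally) and cross-checked in the tests against exhaustive enumeration
of all `2^n` outcomes for `n <= 15`. The upper-tail reading is validated by
an analytic anchor: a saturated population (`x = n = 46`) gives exactly
`0.5^46 = 1.42e-14`.

**MP-score (`mp_score()`).** The older per-complex purity score is included
for comparison. Its published definition survives only as three anchor
points — `+1` for all-positive, `-1` for all-negative, `0` at the background
positive/negative ratio — so the package uses the piecewise-linear
interpolation `(f - f0)/(1 - f0)` for `f >= f0`, else `-(f0 - f)/f0`, where
`f` is the cluster and `f0` the background positive fraction. This honours
every anchor, is monotone in `f`, and reproduces the score's known
pathology (the slope discontinuity at `f0` sharpens as the background grows
imbalanced, so near-balanced complexes can be called monochromatic under
extreme backgrounds). It is deliberately isolated in a single function so a
different algebraic form can be substituted; numeric agreement with the
original implementation is not claimed. A degenerate background
(`f0` of 0 or 1) only admits pure clusters; anything else is an error
rather than a silent extrapolation.

## Thresholds and conventions

* Cutoff filters: lenient `p < 0.05`; intermediate `p < 0.05` and
  `|epsilon| > 0.08`; stringent `(epsilon > 0.16 or epsilon < -0.12)` and
  `p < 0.05`. All inequalities strict; stringent calls are provably nested
  in the other two.
* Cluster retention: `min_interactions = 2` by default. The source
  descriptions of the procedure state "at least two" in one place and "more
  than two" in another; this package follows the former and exposes the
  threshold as an argument.
* Both classification thresholds are strict: a complex is monochromatic
  when `|MP| > 0.5`, and a cluster is *highly monochromatic* when
  `|beta| >` MCI. Consequently, when every cluster is pure the MCI is 1 and
  the highly monochromatic set is empty by construction.
* Duplicate screening orientations (query×array and array×query) are merged
  by averaging `epsilon` and keeping the smaller p-value when the signs
  agree, and the pair is discarded entirely when they disagree —
  a conservative symmetric policy for a case the upstream scoring leaves
  open.
* Gene identifiers are trimmed and matched case-insensitively (mixed-case
  systematic names are common in yeast resources).
* Subsystems are plain gene lists; a complex belongs to a subsystem only if
  *all* its members do, and subsystems with fewer than 2 eligible clusters
  are skipped rather than scored, since a population statistic over one
  cluster is meaningless.

## The synthetic generator

`generate_interaction_data()` emulates an SGA-style screen with planted
ground truth: disjoint complexes (sizes uniform on 4–8, 20 complexes by
default), each intra-complex pair interacting with probability 0.6 and each
inter-complex pair with probability 0.05, so a default screen yields a few
hundred interactions — large enough for stable statistics, small enough
that the full suite runs in seconds. Each cluster gets a majority sign
(positive with probability `f_positive`), and each of its interactions
matches that majority with probability `purity`: `purity = 1` plants pure
clusters, `purity = 0.5` plants pure noise. Magnitudes are log-normal
(median 0.15, `sdlog` 0.6 — straddling the 0.08/0.12/0.16 cutoff scale so
all three filters bite), and p-values are a 90/10 mixture of sub-0.05 and
uniform values for the same reason. Note the *marginal* positive fraction
of a generated screen is `f+·purity + (1-f+)·(1-purity)`, not `f_positive`
itself; the tests check the composition against that model-implied value.

What the generator does **not** emulate: overlapping complexes, correlated
interaction profiles, missing/untested pairs (every emitted row has a score
and p-value), magnitude–sign dependence, and hub-gene degree structure.
Passing parameter recovery on this model therefore validates the
statistical machinery — clustering, weighting, permutation, seeding — not
the biological fidelity of any particular screen.

`expected_mci()` is the independent oracle: it re-simulates the planted
model directly in terms of cluster sizes and binomial sign counts, never
touching the gene-table pipeline. The recovery tests compare the pipeline
MCI *averaged over k = 5 generated datasets* with the oracle mean, at
tolerance `3 * sqrt(sd^2/k + se^2)` where `sd` is the oracle's
between-replicate spread and `se` the Monte-Carlo error of its mean. The
`sd^2/k` term is needed because a single dataset's MCI is itself a random
draw; comparing one realization against the oracle mean at the mean's
standard error alone would reject valid implementations.

## Problem sizes and runtime

The shipped tests use 100-replicate to 1000-replicate permutations on
populations of 10–150 clusters and oracle grids of 300 replicates; the full
suite completes in well under a minute on one core. The permutation test
scales linearly in `b` times the total interaction count, so screens of
tens of thousands of interactions at `b = 1000` remain comfortably
interactive.

## Known limitations

* The MP-score and sMCI per-cluster forms are contract-based
  reconstructions (above); comparisons against numbers produced by the
  original implementations of those scores should be qualitative.
* The permutation pool contains only pairs with a reported score and sign;
  tested-but-noninteracting pairs are unrepresentable and hence excluded.
  If monochromaticity should be judged against the full tested design, the
  null here is conditional on "interaction called".
* No multiple-testing correction is applied across subsystems — the
  per-subsystem reports are descriptive, mirroring standard practice for
  this analysis.
* Between-complex cluster identity assumes complex names are unique;
  the unordered pair id is their lexicographic join.
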