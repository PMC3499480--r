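---
title: "Phylogenetic signal in chemical profiles: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic signal in chemical profiles: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemophylo)
```

## The problem

Chemotaxonomic datasets pair a phylogeny of sampled species with binary
trait tables: presence/absence of alkaloid structural types in each
species' extract, and binarized bioassay outcomes. Two complementary
questions arise. Per trait: is the set of carrier species clumped on the
tree, random, or overdispersed? Across the whole profile: do
phylogenetically close species have similar chemistry? `chemophylo`
answers the first with the Fritz–Purvis D statistic and the second with
Mantel matrix-permutation tests, and ships a synthetic-study generator so
both can be calibrated without any real data.

## The D statistic

For a binary trait on a rooted bifurcating tree, tips carry their 0/1
state and each internal node the unweighted mean of its two daughters,
computed in postorder. The observed change sum `s_obs` is the sum over
internal nodes of the absolute difference between the daughters: a
perfect clade marker contributes a single change (`s_obs = 1`), a trait
scattered over the tips contributes many. The statistic standardizes
`s_obs` between two null expectations,

\[ D = \frac{s_{obs} - \bar{s}_b}{\bar{s}_r - \bar{s}_b}, \]

with \(\bar s_r\) the mean change sum over 1000 uniform permutations of
the tip states (phylogenetically random end, D = 1) and \(\bar s_b\) the
mean over 1000 Brownian-threshold simulations (Brownian end, D = 0).
Significance is read off the same null samples, one-tailed: `P(D = 1)` is
the fraction of permutation change sums at or below `s_obs` (a trait is
significantly structured when ≥95% of them exceed `s_obs`), and
`P(D = 0)` the fraction of Brownian change sums at or above `s_obs`.

Three choices deserve comment:

* **Daughter averaging ignores branch lengths.** The change-count
  recursion uses unweighted daughter means. Branch lengths enter only
  through the Brownian simulation. Because the identical statistic is
  applied to the observation and to both nulls, D self-normalizes and the
  choice of recursion cancels to first order; what matters is using the
  same one everywhere.
* **The Brownian null is realized by rank thresholding.** Each simulation
  draws independent normal increments with variance equal to branch
  length (root value 0, unit rate — D is invariant to both, since a
  location shift or global scaling leaves the top-k ranks unchanged) and
  assigns state 1 to the k tips with the largest values, k being the
  observed carrier count. This enforces the observed prevalence exactly
  in every simulation, and is equivalent to solving for a numeric
  threshold because ties among continuous values have probability zero.
* **P-values are plain fractions, one-tailed.** The decision rule is
  stated in terms of the fraction of null change sums beyond the
  observation, so the default has no add-one correction; `correct = TRUE`
  switches both p-values to the `(count + 1)/(n + 1)` variant.

Polytomies (common in consensus trees) make the sister-clade recursion
ambiguous, so `resolve_polytomies()` replaces each one by a seeded random
sequence of zero-length internal branches. This preserves every patristic
distance, contributes zero Brownian variance on the inserted branches,
and makes runs reproducible. If the denominator
\(\bar s_r - \bar s_b\) is numerically zero — possible on degenerate
trees where the two nulls coincide — the package refuses to report a D
rather than returning an unstable ratio.

Traits carried by fewer than two species (or absent in fewer than two)
are excluded before analysis. This is deliberately symmetric and slightly
stronger than excluding single-carrier traits only: with no variation in
one state both nulls degenerate, so no meaningful D exists. Exclusions
are always reported with counts, never silent.

## Mantel tests and distances

The chemical distance between two taxa is the binary squared Euclidean
distance between their type vectors — exactly the number of alkaloid
types present in one but not the other (a Hamming count, bounded by the
vocabulary size). The phylogenetic distance is patristic (summed branch
lengths). The Mantel statistic is the Pearson correlation of the strictly
upper triangles; the null applies a random taxon permutation
simultaneously to rows and columns of one matrix and recomputes r, 999
times by default.

The sampled p-value uses the add-one convention
`(count + 1)/(n_permutations + 1)` so that p is never zero. A reported
p = 0.002 from a 999-permutation test is only reachable on that
convention's grid, which is why it is the default; the plain fraction is
available via `correct = FALSE`. The test is one-tailed for positive
association (the directional hypothesis that close relatives share
chemistry); `alternative = "two.sided"` is available. For `n ≤ 7`,
`exhaustive_mantel()` enumerates all `n!` permutations and returns the
exact exceedance probability; the unit tests hold the sampled test to the
exhaustive value within a 99% binomial interval.

At genus level, the tree is reduced to maximal single-genus clades. A
polyphyletic genus contributes one entry per clade (labelled `genus-1`,
`genus-2`, … in preorder, so output is stable), rather than being forced
into a false monophyletic group. The clade profile is the union of member
profiles: since the downstream metric is defined on binary vectors, a
count-sum aggregate would silently change the metric, so union is the
only coding consistent with the distance — it is therefore not exposed
as an option. Between-clade phylogenetic distance is the patristic
distance between exemplar tips; on an ultrametric tree every cross-clade
tip pair passes through the same ancestor depth, so the exemplar choice
is provably irrelevant (and the package refuses non-ultrametric input
here unless forced). Singleton-species genera are retained at genus
level; dropping them would discard real profile information and the
exemplar construction handles them naturally.

## Bioassay binarization

AChE activity: screen at 1.0 µg/ml with an inclusive 50% inhibition
cutoff; SERT activity: screen at 5 mg/ml with a strict >85% binding
cutoff; in both assays an extract is finally scored active only when its
IC50 is below 50 µg/ml. A failed screen or an IC50 at or above the bound
codes 0; an absent screening value codes missing. An extract that passed
screening but has no IC50 also codes missing — the protocol determines
IC50 for every screen-active extract, so this situation only arises with
incomplete user data, where refusing to guess is safer than either 0 or
1. `code_bioactivity()` is monotone: raising IC50 can never create
activity, raising the screening percentage can never remove it.

Species without a value for one assay are pruned from that assay's
analysis tree only; all other traits keep the full species set. The
reconciliation report lists every pruned tip.

## The synthetic study

`simulate_profiles()` generates the world the analysis assumes, at the
scale of the motivating dataset: a 108-tip ultrametric Yule tree
(rescaled to unit depth; only the shape matters) carrying 43 genera
painted as true clades with 10% of genera made polyphyletic by tip
relabelling; 9 alkaloid traits of which 2 are singletons; and 2 bioassay
traits with an 8-species missing block in SERT, drawn from the largest
genus to mimic a missing congeneric batch.

Signal is parameterized as a Brownian/random mixture: each informative
trait is drawn from the Brownian-threshold model with probability `w`,
otherwise as a uniform random carrier set. This parameterization is
chosen over, say, a transition-rate model because D itself is defined by
these two endpoints: the long-run mean of estimated D is analytically
`1 − w`, giving recovery tests known targets with no simulation-model
mismatch. The default `w = 0.5` places the study in the moderate-signal
regime where D values spread over (0, 1), matching the situation the
method is designed to discriminate. Informative-trait prevalences default
to 0.40 down to 0.10 in steps — a realistic profile where one or two
types are widespread and the rest progressively rarer; singletons get
exactly one carrier. Bioassay traits are Brownian-threshold draws
accepted only when their Jaccard overlap with an anchor alkaloid trait
reaches 0.2 (AChE is anchored to galanthamine — the classic AChE
inhibitor type — SERT to crinine), mimicking activity driven by
chemistry rather than independent of it.

What the generator does *not* emulate: correlated gain/loss along
biosynthetic pathways, intraspecific variation in profiles, detection
noise in GC–MS scoring, and non-Yule tree shape. A green recovery test
therefore establishes that the estimator is unbiased and calibrated under
its own model assumptions — not that any particular real dataset
satisfies them.

All randomness flows from one master seed; per-trait substreams are
derived from the seed and the trait name, so per-trait results are
identical in any execution order and the whole study (files included) is
byte-reproducible.

## Numerical and testing notes

* Ultrametricity is validated with a relative tolerance (default 1e-6 of
  the maximum tip depth) but never enforced by transformation — dating is
  a modelling decision outside this package's scope; synthetic trees are
  ultrametric by construction.
* The change-sum engine is vectorized over null replicates (one postorder
  sweep per 1000-column state matrix), which keeps 1000/1000-draw
  analyses of a 108-tip study near 0.1 s per trait in pure R.
* Exhaustive Mantel enumeration uses a small tie tolerance (1e-12) when
  counting null correlations at least as large as the observed one, so
  automorphic permutations that reproduce r exactly are not lost to
  floating-point noise.
* Calibration and power figures quoted anywhere in the documentation are
  computed by `tests/testthat/test-acceptance.R` at fixed seeds: mean D
  within ±0.10 of 0 (Brownian traits) and of 1 (random traits) on a
  128-tip tree; 5%-level rejection rates of both D p-values and of the
  Mantel test under their nulls within [0.03, 0.07]; Mantel power ≥ 0.80
  at `w = 0.8` with 100 species and 9 types.

## Known limitations

D is a point estimate with Monte-Carlo error from both nulls; at small
tip counts or extreme prevalence its variance is large, and the
permutation p-value grid is coarse. The Brownian-threshold null assumes a
single continuous liability; threshold traits driven by several pathways
are outside it. The Mantel test is known to have inflated error rates
under strong spatial/phylogenetic autocorrelation structure in *both*
matrices; here it is used exactly as the motivating analysis used it, as
a descriptive permutation test of matrix association.
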