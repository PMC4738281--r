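---
title: "Models and methods behind barcodeDelim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind barcodeDelim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeDelim)
```

`barcodeDelim` turns an aligned COI barcode survey into candidate species
and downstream diversity and diversification analyses. This vignette is the
package's own account of the models it fits, the conventions it adopts
where the literature leaves room, and what its synthetic-data tests do and
do not demonstrate.

## Distances

All divergence computations use the Kimura 2-parameter model. For a pair of
sequences compared over the columns where both carry an unambiguous base
(*pairwise deletion*), with transition proportion $P$ and transversion
proportion $Q$,

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).$$

Pairwise deletion preserves the full per-pair information of a trimmed
barcode alignment and is the common default for barcodes; complete deletion
would discard whole columns for a single ragged record. Ambiguity codes
other than `N` are treated as `N` — COI barcodes rarely carry them, and
fractional-match conventions would complicate the estimator for no benefit.
A *saturated* pair (either logarithm undefined) raises an error instead of
returning a capped value: a silent cap would corrupt the sorted distance
vector that barcode-gap detection scans.

## Trees

Neighbor-joining uses the canonical Q-criterion agglomeration (via
`ape::nj`); negative branch-length estimates, which K2P matrices from real
barcodes routinely produce, are clamped to zero with the deficit moved to a
sibling branch (the Kuhner–Felsenstein convention), preserving local path
lengths. On additive matrices NJ is consistent, and the test suite verifies
exact path-length reproduction on random additive matrices.

Bootstrap supports resample alignment columns with replacement, rebuild the
NJ tree, and count recovered bipartitions; supports are attached to
bipartitions (not node objects), so they are well defined for unrooted
trees and survive midpoint rooting. One root seed spawns per-replicate
substream seeds, making runs reproducible regardless of evaluation order.
Saturated replicates are skipped with a message; more than 10% skipped is a
hard error, since supports would no longer be comparable.

UPGMA (average linkage, node age = half the join distance) serves as the
fallback ultrametric input for the GMYC model when no chronogram is
supplied. It is a fallback, not a recommendation: a chronogram from a
proper dating analysis is always the better input.

## Species delimitation

**Threshold clustering.** The NJ tree is midpoint-rooted (deterministic and
standard for distance trees; the method needs *a* root, and barcode
surveys rarely carry outgroups) and traversed from the root. A clade is one
candidate species iff (a) its maximum intra-clade K2P distance is below the
threshold (default 0.02 — the conventional smallest difference between
unambiguously distinct species in COI barcoding), (b) its minimum distance
to its sister clade is at least the threshold, and (c) its bootstrap
support is at least 70. Rejected clades are descended into; lone tips
become singletons. Condition (b) is vacuous at the root and condition (c)
for tips and unlabelled nodes.

**ABGD.** For each prior intraspecific limit $p$ on a log-spaced grid
(defaults $10^{-3}$ to $10^{-1}$, 10 steps), the sorted pairwise distances
are scanned for the first *barcode gap* reaching beyond $p$: a gap between
consecutive distances wider than $X$ times the local slope (the mean of the
preceding up-to-10 gaps; $X = 1.5$). Distances at or below $p$ are presumed
intraspecific, so the gap's lower edge may sit below $p$ — discarding a gap
that spans the prior would defeat the method. Samples are partitioned into
connected components of the graph linking pairs below the gap's lower
edge, and the procedure recurses within components until stable. The
partition returned by the most priors (*modal partition*) is the
convenience selector; ABGD oversplits at very small priors and undersplits
at very large ones, and the modal choice is the deterministic middle.

**GMYC.** The single-threshold generalized mixed Yule coalescent model
fits, for every candidate threshold age $T$ (the internal node ages of an
ultrametric gene tree), a two-class branching process to the waiting times
$x_i$ between successive branching events:

$$b_i = \lambda_\mathrm{div}\, n_{d,i}^{\,p_\mathrm{div}} +
        \lambda_\mathrm{coal} \sum_k n_{k,i}^{\,p_\mathrm{coal}},
\qquad
\ln L(T) = \sum_i \big[\ln b_i - b_i x_i\big],$$

where nodes strictly older than $T$ are between-species events, the node at
$T$ is the oldest within-cluster coalescence, within-cluster branches are
the proper descendants of each cluster MRCA, and stems plus singleton
branches stay in the diversification class. The null model is a single
class $b_i = \lambda n_i^p$ (its $\lambda$ is profiled out in closed form).
Parameters are maximized by bounded quasi-Newton iterations from multiple
starts ($\lambda$ started at the Yule MLE; $p$ at 1, Yule-like, and 2,
coalescent-like; bounds $\lambda \ge 10^{-8}$, $p \in [0.01, 4]$).
*Entities* are the lineages crossing the ML threshold; the confidence set
collects thresholds within 1.92 log-likelihood units of the maximum; the
likelihood-ratio statistic is referred to $\chi^2_3$ (5 vs 2 parameters,
the threshold not counted). With the threshold at the root age the mixed
model collapses to the null family, so $\ln L_\mathrm{GMYC} \ge
\ln L_\mathrm{null}$ holds by construction.

Two properties of the method itself, measured with this implementation and
worth knowing before trusting any single number:

* *Exact entity recovery is not guaranteed.* On simulated surveys at the
  package defaults (20 species, 5 individuals each, $\theta = 0.002$,
  species divergences $\ge 0.05$), the ML entity count equals the truth on
  about two thirds of draws; the 1.92-unit confidence set covers the truth
  on over 90%. The failures are genuine maximum-likelihood preferences:
  when one species' coalescent genealogy runs deep, splitting it gains a
  fraction of a log-likelihood unit. Consensus with the distance-based
  methods absorbs these splits.
* *The LR test is mildly anticonservative.* On single-population Kingman
  coalescent trees ($n = 40$) the df-3 test rejects at the 5% level in
  roughly 10% of replicates — the threshold is optimized but not counted as
  a parameter. Treat marginal p-values accordingly.

**Consensus.** A pair is conspecific iff a strict majority of input
partitions says so; with an even number of methods a tie lumps (the
conservative direction for species counts). Species are the connected
components of the conspecificity graph; pairs overturned by this transitive
closure are counted and reported.

## Ecology summaries

Divergence-by-band assigns each *individual* to the half-open 500-m band
containing its own collection elevation (half-open edges prevent double
counting), then summarises conspecific and heterospecific pair distances
within bands. Richness-by-band instead counts a *species* in every band its
observed elevation range intersects — individual-based binning matches
per-band pair summaries, range-based binning matches richness curves, and
the two questions genuinely need different tallies. Allopatry means
different site identifiers (sites are far apart by sampling design);
endemic means collected at a single site — the strictest objective reading.
Grid richness counts distinct species per lat/lon cell with the origin at
integer degrees; it is the numeric layer behind a density map, and
rendering is out of scope.

## Diversification rates

Five models are fitted to the branching times $t_1 > \dots > t_{n-1}$ (with
$a_k$ the duration with $k$ lineages): pure birth ($r = \lambda$, MLE
closed-form $\hat\lambda = (n-2)/\sum_k k\,a_k$), birth–death (Nee et al.
likelihood conditioned on the root age and survival of both root lineages,
written with the same $\ln(n-1)!$ constant as the pure-birth model so
$\mu = 0$ reduces to it exactly), logistic density dependence
$r = \lambda_0(1 - k/K)$ with $K > n - 1$, exponential density dependence
$r = \lambda_0 k^{-x}$ with $x \ge 0$ (decline; $x = 0$ is pure birth at
the boundary), and the two-rate Yule model with the shift searched over
the observed branching times and per-segment closed-form rate MLEs. AIC
uses the parameter counts 1, 2, 2, 2, 3 ($t_\mathrm{shift}$ counted). The
rate-constancy statistic is
$\Delta\mathrm{AIC}_{RC} = \mathrm{AIC}_{RC} - \mathrm{AIC}_{RV}$, the best
rate-constant minus the best rate-variable AIC.

Two calibration facts, again measured with this implementation:

* Under rate constancy the naive decision rule
  "$\Delta\mathrm{AIC}_{RC} > 0$" fires on roughly 60–70% of pure-birth
  trees ($n = 100$): the shift search of the two-rate model inflates its
  likelihood beyond a fixed 2-parameter penalty. The statistic orders
  models; its null distribution should be simulated before it is used as a
  test, which is why the package reports the statistic rather than a
  verdict.
* The ML shift time of the two-rate model has a sampling spread of a few
  inter-event intervals when few events predate the shift (median error
  ~7% of the root age at a $0.5 \to 2.0$ shift near half the root age,
  $n = 200$); it recovers the exact containing interval on about half of
  draws.

The relative cladogenesis test evaluates, at each internal node with $k$
contemporaneous lineages jointly leaving $n$ tips, the equal-rates Markov
probability that a lineage leaves at least $r$ descendants,
$p = \binom{n-r}{k-1}/\binom{n-1}{k-1}$ (verified against exhaustive
composition enumeration). One test per node is performed on its larger
daughter clade, and the Bonferroni divisor is the number of node tests —
the family is the nodes actually tested, not a notional per-daughter
doubling that would double-count the same split.

## The synthetic-data generator

The generator emulates a high-elevation conifer-aphid barcode survey:

* **Species tree** — Yule, default 20 species, root rescaled to 0.10
  substitutions/site. Raw node ages are mapped affinely onto
  $[0.025, 0.10]$: the 0.025 *minimum species age* reproduces the barcode
  gap (intraspecific $\lesssim 0.01$, interspecific $\gtrsim 0.05$) that
  real delimitable communities show and that the study regime requires. A
  bare Yule tree would place sister splits arbitrarily close to the
  present, a regime in which no barcode method can work and which the
  emulated kind of survey, by construction of its sampling protocol, does
  not present.
* **Gene tree** — within each species, a neutral coalescent with rate
  $j(j-1)/\theta$ for $j$ lineages ($E[\mathrm{TMRCA}] = \theta(1 - 1/m)$;
  default $\theta = 0.002$), censored to coalesce below the species' stem
  by whole-species resampling. This keeps species monophyletic — the regime
  the delimitation methods assume — and is a stated limitation: no
  incomplete lineage sorting across species boundaries, no migration, no
  hybridization.
* **Sequences** — 658 sites, i.i.d., two substitution classes with
  transition/transversion rate ratio $\kappa = 8$, root drawn from the
  AT-biased composition (T 0.39, C 0.15, A 0.36, G 0.10). The process is
  symmetric, so K2P estimates are consistent for path lengths regardless of
  the root composition; there is no rate heterogeneity across sites by
  default, keeping expectations analytic.
* **Metadata** — 25 sites drawn in a southwest-China-like bounding box
  (lon 98–105, lat 26–34, elevations 1500–5000 m), species assigned small
  home site sets from a shared pool (so sympatry arises by sharing), one
  host genus per species with weights favouring spruce and fir, and one of
  three feeding sites — enough structure that every cell of the 2x2x2
  divergence analysis is realizable.

Passing tests on these data show that the algorithms are implemented
correctly and recover planted truth in the regime they assume. They do not
show robustness to pseudogenes, sequencing error, introgression,
paraphyletic species, or non-neutral markers — none of which the generator
simulates.

## Numerical conventions and degenerate inputs

Ultrametricity is checked with relative tolerance $10^{-6}$; tied node ages
are broken by jitter below $10^{-9}$ of the root age (reported). NJ Q-matrix
ties resolve to the lowest index pair. Optimizers are bounded L-BFGS-B with
multiple starts; the likelihood-ratio statistic is clamped at zero against
optimizer jitter. Problem sizes in the test suite (100-barcode surveys,
100-replicate bootstraps, 200-tree calibrations) were chosen as the
smallest sizes at which the statistical expectations they check are sharp.

## Known limitations

Single-locus delimitation only (no multi-locus models); single-threshold
GMYC (no multiple thresholds); no incomplete-sampling corrections in the
rate models; UPGMA fallback is a poor substitute for a real chronogram; the
consensus is majority-rule over pairs and can, like any such rule, be
overturned by transitive closure on pathological inputs (it reports when
that happens).
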