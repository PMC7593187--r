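---
title: "Methods: phylogeography, ensemble suitability modeling, and haplotype risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogeography, ensemble suitability modeling, and haplotype risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refugia)
```

# Scope

`refugia` implements an integrated workflow for asking where the genetic
diversity of a cold-adapted mountain species came from and where it is going:
mitochondrial haplotype diversity and structure across disjunct mountain
regions, an ensemble climate-suitability model on a coarse occupancy lattice,
millennial hindcasting to locate long-term climate refugia, and future-scenario
projection summarized as a per-region haplotype-risk statistic. The package
assumes sequences arrive already aligned; alignment construction, chromatogram
QC, molecular dating, and the acquisition of real climate or atlas data are
outside its scope.

# Genetic diversity measures

Sequences are filtered by **complete deletion**: any alignment column carrying
a character outside `{A,C,G,T}` in any record is removed before haplotypes are
called. This makes haplotype identity well defined — two records belong to the
same haplotype exactly when they agree on every retained site. A
pairwise-style alternative was considered and rejected for the default because
it makes "same haplotype" intransitive; the `keep-all` policy is available
when the caller has pre-cleaned data.

For a scope with $n$ sequences and haplotype frequencies $p_i$:

* **Haplotype diversity** uses the sample-size-corrected estimator
  $H_d = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$, which equals the
  probability that two sequences drawn without replacement carry different
  haplotypes. The correction matters at the small per-region sample sizes
  (5–50) typical here, and is the form used by the standard population-genetics
  tools this module is meant to interoperate with.
* **Nucleotide diversity** $\pi$ is the mean number of per-site differences
  over all unordered pairs, divided by the retained length $L$. It is computed
  column-wise (counting concordant pairs per site) so the cost is $O(nL)$
  rather than $O(n^2 L)$; the test suite verifies exact agreement with the
  brute-force pairwise definition.
* **Unique haplotypes** $H_u$ are those with nonzero count in exactly one
  region. Summed over regions this is bounded by the total haplotype count,
  which the tests assert on random panels.

Single-sequence scopes report $H_d = \pi = 0$ with a warning rather than an
error, so a thin region does not abort a whole-table computation.

## AMOVA

Population differentiation is summarized by the two-level analysis of
molecular variance on squared pairwise Hamming distances. With total sum of
squares $SS_T = \sum_{i<j} d_{ij}^2 / N$ and within-group sums computed
per group, the among/within variance components use the standard
mean-square decomposition with the unbiased coefficient
$n_0 = (N - \sum_g n_g^2/N)/(G-1)$ for unequal group sizes, and
$\phi = \sigma^2_a / (\sigma^2_a + \sigma^2_w)$. Groups default to one
population per mountain region. The null distribution permutes individuals
across groups with sizes held fixed; the p-value carries the $+1$ correction
$p = (\#\{\phi^* \ge \phi\} + 1)/(B+1)$ with $B = 999$ permutations by
default, so reported p-values are never exactly zero. A 500-replicate
calibration under an exchangeable no-structure null (two groups of ten drawn
from a shared haplotype pool, 199 permutations each) is part of the
acceptance suite and holds the $\alpha = 0.05$ rejection rate inside
$[0.03, 0.07]$.

## Haplotype network

The network is a **minimum-spanning network**: a minimum spanning tree on
pairwise Hamming distances, plus every non-tree edge whose weight ties the
heaviest edge on the tree path between its endpoints, so equally parsimonious
alternative connections are kept (the familiar loops of statistical-parsimony
networks). The statistical-parsimony connection limit is deliberately **not**
re-derived from a coalescent probability formula; it is a plain user
parameter, defaulting to `"none"` because the study design this package
follows displays all haplotypes connected. Edges are annotated with
substitution counts, and the tests check that no network path undercuts the
direct Hamming distance between its endpoints.

# Suitability modeling

## Extreme-cell features

Occupancy lives on a coarse lattice (50-km squares by convention) while
climate is fine-grained (~5-km cells). A montane species occupies the coldest
corner of a coarse square, not its average, so each coarse cell is described
by the **minimum and maximum over its fine cells** of four seasonal
variables — mean temperature and mean precipitation of the coldest and warmest
quarters — giving eight features (e.g. `T_warmQ_min`, the summit summer
temperature of the square). Coarse cells with no valid fine climate are
masked, propagate as `NA` probabilities, and are excluded from ranking and
risk computations.

## Pseudo-absences

True absences are unknowable at continental scale, so background cells are
sampled as pseudo-absences — but only within a 250-km buffer of some presence,
which keeps "absences" out of remote mountain systems the species simply
never reached. The default draw is 3 pseudo-absences per presence (uniform,
without replacement, seeded); the candidate count caps the draw. Distances are
Euclidean on planar cell centers in km, which is exact for the synthetic
worlds; geographic data would substitute great-circle distances.

## The ROC-gated committee

Four model families are fitted to a single stratified 70/30 split:
ridge-regularized logistic regression (glmnet, fixed light penalty
$\lambda = 0.01$ on standardized features), a spline additive logistic model
(mgcv, $k \le 4$ per smooth with shrinkage selection), a probability random
forest (ranger, 500 trees), and a rectilinear surface-range envelope scoring
1 inside the 2.5–97.5 percentile bounds of the training presences. The roster
stands in for the larger committees of ensemble-SDM platforms; the point of
the module is the **gate**: a member joins the ensemble only if its holdout
AUC exceeds 0.85, and prediction is the unweighted mean of included members'
probabilities (an AUC-weighted mean sits behind a flag, as does re-gating at
a different threshold without refitting). Standardization parameters come
from training rows only. AUC itself is the exact Mann–Whitney rank statistic
(ties count half), verified in the tests against brute-force pair counting.
A family that fails to fit is excluded with a warning rather than aborting
the committee; an ensemble with no surviving member is an error, not a
silent fallback.

Spatial autocorrelation of model inputs or residuals can be screened with
`morans_i()` (rook or inverse-distance weights, row-standardized, normal
approximation under randomization).

# Hindcasting and the stability surface

Paleoclimate anomalies (paleo minus modern, per variable) arrive on a coarse
lattice and are **delta-downscaled**: bilinearly interpolated to fine cell
centers and added to the modern baseline, with precipitation floored at zero.
Fine cells beyond the anomaly grid's extent take the nearest-edge value with
a warning. For uniform anomalies this reproduces coarse-cell means exactly,
which the tests assert. The downscaling is intentionally the plain
change-factor method — no topographic correction or spline refinement — since
the synthetic anomaly fields it is exercised against are smooth by
construction.

Each of the 21 millennial slices (glacial maximum at 21 ka through 1 ka) is
downscaled, featurized, predicted, and then clipped by that slice's ice
mask: ice-covered cells take probability 0 and keep a flag. The present-day
map is appended as the 22nd layer. The **stability surface** sums
probabilities cell-wise over the 22 maps (ice contributes 0 — clipping
conventions differ between studies, and zero-contribution is the conservative
reading for a species that cannot occupy ice) and flags the top
$\lceil 0.30 \cdot N_{\text{unmasked}} \rceil$ cells as the long-term
climate refugia. Ties at the cut break deterministically by ascending cell
index; `include_ties = TRUE` retains all tied cells instead. Slice order is
immaterial to the sums, and adding an all-zero layer changes nothing — both
are tested properties.

# Future projection and haplotype risk

Probabilities become presence/absence at a threshold; **suitable means
probability ≥ threshold**, so the range-edge cell that defines the threshold
remains suitable at present (a strict inequality would evict it). The
threshold is either fixed (study convention 0.49, the ensemble probability at
the species' lowest-elevation occupied square) or derived as the current
probability of the occupied cell with minimum mean elevation.

Cell fates: occupied and future-suitable is *persistence*; occupied and not
is *extinction*; unoccupied and future-suitable is *colonization*; otherwise
*absent*. Per-region **range change** is
$100 (n_{\text{persisting}} - n_{\text{occupied}}) / n_{\text{occupied}}$,
computed over currently occupied cells only: colonization is reported
separately, never netted, because projected gains at unoccupied cells are
speculative in a way observed occupancy is not. A region is **lost** only
when *all* its occupied cells go extinct, and

$$H_r = \sum_{r\,:\,\text{lost}(r)} H_u(r)$$

counts the region-unique haplotypes that would have no remaining climatically
suitable square. $H_r$ is monotone in the threshold (a stricter suitability
bar can only lose more regions), which the tests exercise. Subregions can be
pooled for spatial reporting while keeping separate genetic bookkeeping via a
region-alias map (the packaged worked example pools three Alpine subranges).
The elevational pattern of change is summarized by an ordinary least-squares
regression of per-cell probability change on mean cell elevation, with the
usual $R^2$, $F_{1,n-2}$ and two-sided p.

# The synthetic world

The generator exists so that every stage has a machine-checkable ground
truth without any downloads. It emulates the *shape* of the study data, not
its realism:

* **Landscape**: 20 × 20 coarse cells of 50 km, each over a 10 × 10 block of
  fine cells; elevation is a 100-m plain plus 13 Gaussian ridges of 1250–2600
  m whose Voronoi cells define the 13 regions. Temperature follows a −6.5
  °C/km lapse rate from sea-level bases (16 °C warm quarter, 2 °C cold
  quarter) plus smooth seeded noise (0.4 °C); precipitation has a 150 mm/km
  orographic gain (noise 15 mm, floored at 0). These are round mid-latitude
  mountain values chosen once for plausibility, not fitted to anything.
* **Truth**: suitability is logistic in `T_warmQ_min`
  ($\beta_0 = 8.1$, $\beta = -0.9$), so the 0.5-probability contour sits at
  9 °C summit summer temperature (~1100 m); presences are the superlevel set
  at threshold 0.5 (239 occupied squares under the default seed).
* **History**: temperature anomalies ramp linearly from −4 °C at 21 ka to
  zero; ice covers coarse cells whose cold-quarter temperature drops below
  −12 °C. Future scenarios warm uniformly by +1 °C (low) and +2.5 °C (high),
  matching the ~1 °C vs ~2–3 °C bracket of the usual low/high concentration
  pathways.
* **Sequences**: a seeded random 649-bp root; each planted haplotype
  substitutes 1–5 *globally distinct* positions (sampled without
  replacement), so haplotypes are guaranteed distinct and planted Hamming
  distances are exact. The default panel emits 215 sequences in 13 regions
  collapsing to 31 haplotypes, 27 of them region-unique and 4 shared across
  region sets — a star-like continental phylogeography. The round trip
  through the haplotype module recovers the planted per-region counts
  exactly.
* **Planted extinction**: from the closed form of the true logistic, the
  generator computes the uniform warming at which each region's most
  resistant occupied cell crosses the suitability threshold and returns the
  offset that extinguishes exactly the first-crossing region. The
  `planted_loss_regions()` preset moves the region carrying six unique
  haplotypes onto the isolated low ridge so this recovery check runs with a
  nonzero planted count.

What the generator does **not** emulate — coalescent genealogies, spatially
realistic climate fields, observation error in occupancy, regionally varying
niches — bounds what passing tests demonstrate: they validate the estimators,
the gating/combination logic, and the bookkeeping from maps to $H_r$, not the
ecological fidelity of any particular fitted surface on real data.

Everything is reproducible bit-for-bit from the spec's master seed; each
stage derives a fixed sub-seed, and package functions restore the caller's
RNG state.

# Numerical choices and problem sizes

* Distances are integer Hamming counts; no floating-point ambiguity enters
  the network or AMOVA.
* The AMOVA permutation p floors at $1/(B+1)$; calibration uses 500
  replicates × 199 permutations at $n = 20$, a size where the null is dense
  enough to measure size without being slow.
* Committee tests run at a few hundred labeled cells; the full-world
  ensemble-recovery check uses the default 400-cell world, where a fit takes
  a few seconds. The pipeline-level tests use a 10 × 10 coarse world with a
  5 × 5 fine factor.
* `NA` propagates: masked cells never enter training rows, ranked pools, or
  occupied-cell counts; tests pin the masking behavior at each stage.
* Ties: AUC ties count half; stability ties at the flag cut break by cell
  index (or are all retained behind the flag); haplotype ids are assigned by
  first appearance, making every output deterministic at fixed seed.

# Limitations

The committee is four families, not a full ensemble platform roster, and no
variable-importance analysis is provided beyond member AUCs. The downscaler
is the plain change-factor method. Range change ignores colonization by
design (flagged, not netted). mtDNA haplotypes are treated as neutral markers
of colonization history — the package deliberately does not model per-haplotype
niches, so $H_r$ measures exposure of unique variants to regional loss, not
adaptive consequence. Real-data thresholds (like the 0.49 range-edge value)
are study-specific conventions: deriving them from a different region or a
different binarization rule can change which marginal regions count as lost,
and therefore $H_r$.
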