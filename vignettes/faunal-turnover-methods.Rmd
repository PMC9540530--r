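---
title: "Measuring losses, gains, and net change in regional mammal diversity"
author: "faunadiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring losses, gains, and net change in regional mammal diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faunadiv)
```

## The question and the model

Regional mammal faunas have been reshaped over the last eight millennia by
two opposing processes: extirpations remove species from a region, while
reintroductions, natural recolonizations, range expansions, and human
introductions add them. Whether a region ends up less diverse than it was
at the mid-Holocene baseline depends not just on how many species moved in
and out but on *which* ones — how evolutionarily distinct and how
functionally distinct they are. `faunadiv` quantifies this balance with
three complementary metrics, all scaled to the same `[0, 1]` interval so a
region's taxonomic, phylogenetic, and functional trajectories can be read
side by side:

* **Scaled species richness** — the assemblage size divided by the total
  species pool (every species recorded in any region at any time).
* **Scaled phylogenetic diversity** — Faith's PD: the summed branch
  lengths of the minimal subtree spanning the assemblage's tips, rooted at
  their most recent common ancestor (edges from that ancestor to the tree
  root are excluded). PD is computed on every tree of a dated-tree
  ensemble, divided by that tree's total branch length, and averaged; the
  across-tree standard deviation is reported alongside.
* **Scaled functional richness (FRic)** — the volume of the convex hull
  the assemblage spans in a functional trait space, divided by the volume
  of the hull of the entire species pool.

### The status-category algebra

Each (species, region) pair carries one of five historic categories —
persisting native, extirpated native, regained native (recolonized or
reintroduced; no human agency implied), natural colonist, introduced — plus
an optional `FUTURE_POTENTIAL` overlay marking species that *could* be
restored: regionally extirpated species still extant elsewhere, or globally
extinct species with a living surrogate (e.g., Heck cattle for the
aurochs), which are treated as carrying the ancestor's traits and
phylogenetic position. The overlay is kept separate from the historic
record because a future-restorable species is, by definition, also part of
the region's 8000 BP assemblage; a single exclusive category could not
express both facts at once.

Assemblages derive mechanically from the categories:

* 8000 BP = persisting + extirpated + regained;
* 2020 = persisting + regained + colonists + introduced;
* future scenario = 2020 + the overlay;
* 1945 (used by the "Anthropocene" comparison) = persisting, plus
  extirpations dated *after* 1945, plus regains/colonizations/introductions
  completed *before* 1945. Events carry only a recent/older dichotomy at
  1945, not calendar years; for a regained species the flag dates the
  regain, and its loss is taken to precede 1945 whenever the regain is
  recent. This is the one place the single-flag representation is lossy
  (a loss *and* regain both after 1945 cannot be expressed), and it is the
  reason `recent` is mandatory for every change event.

### The loss/gain/net decomposition

For a region with baseline set $S_0$, loss set $L$ (extirpated plus
regained species — regained species were lost before they returned), and
2020 set $S_1$, define $S_p = S_0 \setminus L$ and, for any metric $D$:

$$\text{loss} = D(S_p) - D(S_0) \le 0, \qquad
  \text{gain} = D(S_1) - D(S_p) \ge 0, \qquad
  \text{net} = \text{loss} + \text{gain} = D(S_1) - D(S_0).$$

Losses are applied before gains; the reverse order would change the two
panel values for PD and FRic (though never their sum), and the
losses-then-gains order matches the narrative sequence in which the
decomposition is read. Because $D(S_p)$ is evaluated once and shared, the
additivity `net = loss + gain` holds to machine precision, and a regained
species deliberately appears in both panels — that is what makes the
decomposition additive. For richness the decomposition is computed as a
single division of the signed count difference, so it equals
$\pm|\cdot|/\text{total}$ exactly.

The future scenario reports, per metric, $D(S_1 \cup F) - D(S_1)$ where
$F$ is the overlay set; it is non-negative for richness and PD by
monotonicity, and zero for regions (mostly islands) whose losses were
surrogate-less global extinctions.

## The trait space

Five trait groups describe each species: body mass (g), seven diet
percentages summing to 100, a foraging-stratum label, three
activity-period flags, and a set of habitat flags. Gower dissimilarity
handles this mixture: continuous variables contribute range-normalized
absolute differences, categorical and binary variables contribute 0/1
mismatches, and each trait *group* receives total weight 1 split equally
among its variables (each diet variable weighs 1/7, each activity flag
1/3, and so on), so no group dominates by having more columns. Body mass
enters as log10(mass): masses span five orders of magnitude, and on the
raw scale the largest species would carry essentially all of the mass
signal. Range normalization is Gower's own standardization; no additional
z-scoring is applied, since any affine rescaling is absorbed by the range
division. Variables that are constant across the whole pool carry no
information and are dropped with a warning; missing values are dropped
pairwise with weight renormalization.

The resulting matrix is generally non-Euclidean, so its element-wise
square root is taken before ordination — a transform that in practice
drives the negative eigenvalue mass to (numerical) zero on tables of this
structure — and principal coordinates analysis embeds the species into
`k = 5` axes (coordinates are eigenvectors scaled by the square root of
their eigenvalues, axes oriented so the first nonzero loading is
positive). `pcoaAxes()` refuses to proceed when the most negative
eigenvalue exceeds 5% of the largest, advising the transform instead of
silently discarding structure; no Cailliez or Lingoes correction is
applied. The axis count is configurable (`k` in `buildTraitSpace()` and
`--k-axes` in the CLI); published analyses of this kind report
insensitivity to the choice, and the package's own results keep `k = 5`.

## Hull geometry

Functional richness requires k-dimensional convex hull volumes, and the
occupancy-overlap statistic requires the volume of the intersection of two
hulls. Both are computed exactly by an incremental (beneath-beyond) hull
engine with scale-relative tolerances (`src/convexhull.cpp`), which
returns facet half-spaces alongside volumes:

* A hull is **undefined** — reported as `NA`, never as zero and never as
  an error mid-pipeline — when the assemblage does not exceed the axis
  count (`n <= k`) or the point cloud is affinely degenerate. This mirrors
  the dimensionality constraint inherent in hull-based FRic; undefined is
  deliberately kept distinct from "zero volume". No general-position
  jitter is applied; degeneracy is handled by rank checks so results stay
  deterministic.
* **Intersection volumes** are computed piecewise. Hull A is decomposed
  into pyramid simplices, one per facet with the apex at an interior
  point, and only the facets of B that actually cut into A are retained
  (a facet whose half-space contains every vertex of A cannot cut the
  intersection; containment in either direction is short-circuited
  exactly). Each simplex is then classified: entirely inside B it
  contributes its full volume, entirely beyond some facet of B it
  contributes nothing, and the straddling minority is clipped exactly —
  the simplex's own facets plus its active cutting planes form a small
  half-space system whose volume is obtained by polar duality around an
  interior point of the piece, integrating exact pyramids over the dual
  incidence structure. Any strictly interior point yields the same exact
  polytope, so only the feasible/infeasible decision depends on the
  interior-point search (deterministic candidates polished by
  Nelder-Mead on the concave minimum-slack function); an infeasible piece
  is degenerate and contributes 0. The piecewise scheme keeps every
  subproblem small even when the full intersection polytope has
  combinatorially many vertices, which real five-dimensional assemblage
  pairs readily produce, so time and memory stay bounded. Disjoint or
  merely touching hulls give overlap 0.
* Numerical accuracy: volumes and intersections are machine-exact in 2-3
  dimensions and accurate to about one part in $10^4$ for adversarial
  five-dimensional intersections of large clouds (verified against
  rejection-sampling Monte Carlo oracles in the test suite); that is far
  below the 2-3 significant figures at which the diversity metrics are
  interpreted.

The per-region occupancy overlap reported in the diversity table is the
fraction of the 8000 BP hull's volume still inside the 2020 hull — a
measure of how much of the *original* functional space remains occupied,
independent of how much new space was added.

## The synthetic-data generator

No species lists, traits, or trees are bundled: the generator produces
complete, self-consistent input bundles with the statistical structure the
analysis assumes, and a deterministic continental fixture. The defaults
describe the study conditions the pipeline is designed for — a pool of 228
species over 45 regions, roughly 40% of them islands:

* **Trees**: pure-birth (Yule) ultrametric trees via `ape::rphylo` with
  zero extinction, 100 per ensemble by default (full-scale analyses use
  1000; dating realism is irrelevant to metric correctness, which is why
  the simplest ultrametric generator is used).
* **Traits**: log10 body mass normal with mean 2 (100 g) and SD 1;
  volant species (8%) drawn small-bodied; diets as Dirichlet draws
  (concentration 0.5, giving realistic specialist-heavy profiles) rounded
  by largest remainder to integers summing to 100; 12 species flagged
  globally extinct, half with surrogates.
* **Status**: islands draw fewer natives (mean 25 vs 120) and experience
  proportionally more extirpation (0.20 vs 0.06 per native) and
  introduction (Poisson mean 12 vs 8); regains occur for 20% (islands) or
  35% (continental) of extirpated, globally extant natives; change events
  are recent with probability 0.5. Globally extinct species are extirpated
  wherever native and never introduced; every restorable loss enters the
  future overlay. The baseline/2020 set identity holds by construction.

These choices make islands depauperate at baseline and net gainers by
2020 — the qualitative pattern the pipeline is designed to resolve — and
the test suite asserts only the *sign* of that relationship. What the
generator does not emulate: real biogeography (no spatial autocorrelation,
no land-bridge vs oceanic island distinction), trait covariances beyond
the volancy-mass link, phylogenetic signal in traits or in extirpation
risk, and source-database disagreement. Passing tests therefore
demonstrate the machinery is correct under known conditions, not that any
particular empirical estimate is reproduced from real data.

The **continental fixture** (`continentalFixture()`) is a single-region
bundle frozen under an internal seed: 228 species of which 198 are present
at 8000 BP, 17 extirpated region-wide (12 globally extinct, 3 of those
with surrogates) and 30 introduced, hence 211 in 2020 and scaled richness
moving from 0.87 to 0.93. These counts reproduce the published continental
pool arithmetic and anchor the fixture tests; its PD and FRic values are
properties of its synthetic trees and traits, not of any published
phylogeny.

## Numerical and reporting choices

* Problem sizes: the test suite runs the full 45-region, 228-species
  configuration with 25-tree ensembles, and geometry oracles use clouds of
  20-40 points; the acceptance script uses the 100-tree default.
* Ties in the cross-region summary: a region counts as "no change" when
  `net == 0` exactly for richness (an integer-difference quotient) and
  when `|net| < 1e-9` for PD and FRic, where only identical species sets
  produce mathematical ties.
* Medians and ranges are reported at full precision and rounded only at
  display time.
* Per-tree rescaling: PD ratios are formed within each tree and then
  averaged, rather than averaging raw PD and dividing by the mean total
  length. The per-tree form is invariant to rescaling any single tree's
  branch lengths and keeps the full-assemblage value at exactly 1;
  `scaledPD(..., perTree = FALSE)` exposes the other convention for
  sensitivity checks.
* Subgroup analyses (`large_nonvolant`: strictly over 2 kg and not
  volant; `small_nonvolant`: 2 kg or under, not volant — the boundary is
  assigned to the small group so the two partition the non-volant pool)
  restrict every assemblage before the metrics are computed, while the
  scaling denominators stay global, so subgroup change values remain
  comparable with the main run.

## Known limitations

* The 1945 reconstruction is approximate for species lost *and* regained
  after 1945 (see above).
* Hull-based FRic is undefined for assemblages of `k` or fewer species;
  depauperate islands can therefore have `NA` functional metrics at the
  baseline, and such regions are excluded from FRic summaries rather than
  imputed.
* Intersection volumes in five dimensions carry ~0.01% numerical error
  for large, strongly interpenetrating clouds, and such cases are the
  slowest computation in the package (tens of seconds when two large
  independent clouds interpenetrate heavily).
* The generator's island/continental contrast is a two-level caricature;
  it supports sign-level pattern checks, not effect-size calibration.
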