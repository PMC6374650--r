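---
title: "Spatial rarity classification: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial rarity classification: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Rarity in the Rabinowitz sense is a typology, not a single score: a
species is placed on three binary axes — geographic range (Wide vs
Narrow), habitat specificity (Broad vs Restricted) and local population
size (Large vs Small) — giving eight classes of which seven are forms
of rarity and one (`W/B/L`) is "common". The classical inputs for these
axes are literature and expert knowledge. `rarityframe` instead
estimates all three from the one thing large floristic surveys actually
provide: presence-only occurrence points, plus a categorical landcover
raster for the habitat axis. This trades fidelity for coverage — every
species with at least two records gets classified — and the package is
explicit about where that trade bites (see *Limitations*).

## The three indices

For a species with occurrence points $p_1,\dots,p_n$ (exact coordinate
duplicates collapsed first):

- **Range**: $D_{\max} = \max_{i<j} d(p_i, p_j)$, in km. A
  maximum-distance proxy is preferred over a convex-hull area because
  it is defined from two records upward, and the two agree well in
  practice: `range_size_agreement()` re-classifies the hull-eligible
  species (≥ 3 unique points) by hull area and reports the fraction
  receiving the same narrow/wide label.
- **Local abundance**: $D_{\max} / D_{\min}$, where
  $D_{\min} = \frac1n \sum_i \min_{j \ne i} d(p_i, p_j)$. Since every
  nearest-neighbour distance is at most $D_{\max}$, the ratio is ≥ 1,
  with equality for a two-point species. The ratio is scale-free:
  locally dense point clouds score high regardless of range extent.
- **Habitat specificity**: the count of distinct non-nodata landcover
  classes among the cells containing the points. Points off-grid or on
  nodata are excluded with a warning, never silently.

Distances are haversine great-circle distances with Earth radius
6371.0088 km for `lonlat` data and Euclidean for `planar_km` data. The
coordinate mode is a dataset-level declaration, never inferred: silently
confusing degrees with kilometres is the classic failure mode of this
kind of pipeline, so mixing is impossible by construction. Hull areas
for `lonlat` data are computed after a Lambert azimuthal equal-area
projection centred at the point centroid — area-true at the
country-scale extents this method targets.

Duplicate coordinates are collapsed *before* distances because repeat
visits to one site would otherwise drive $D_{\min} \to 0$ and make the
abundance ratio undefined; a species whose records all collapse to a
single point is excluded with a warning and reported separately, never
silently dropped from denominators.

## Cutoffs and class assignment

Each index is binarized at its arithmetic mean ("average" is the
operative word in this tradition; medians are deliberately not
offered). Two modes exist because the method's own description is
ambiguous between them:

- `within_group` (default): the range cutoff is the mean $D_{\max}$
  over all species; abundance and specificity means are then taken
  *within* the narrow and wide groups separately. This matches how the
  classification is actually drawn in the source analyses (separate
  cutoff lines for the narrow and wide panels).
- `global`: one mean per index over all species. When the two groups
  happen to share identical means the modes coincide, which the test
  suite checks.

A value exactly at a cutoff goes to the non-rare side (Wide / Broad /
Large): rarity labels should be conservative, and the underlying
description is silent on ties. Assignment is a pure function of the
index row and the cutoff set — no hysteresis; reclassifying after
removing species changes labels only through the recomputed cutoffs.

## Richness and congruence mapping

Occurrences are binned into half-open square cells
($[x_0 + i s, x_0 + (i+1) s)$); a cell's richness is the number of
*distinct* species with at least one record in it, never the record
count. "Top 20% of richness areas" is interpreted as the top 20% *of
occupied cells* ranked by richness, with all ties at the boundary value
included. The occupied-cell base was chosen because unsurveyed empty
cells dominate any national grid and a quantile over all cells would
select almost everything surveyed; tie inclusion keeps the selection
deterministic under heavy ties. The congruence map counts, per cell,
how many groups' top sets contain it; its area summary multiplies cell
counts by the nominal cell area (10 km cells → 100 km²) and reports
both exact and integer-rounded percentages plus cumulative "≥ level"
rows.

## The synthetic world

`generate_archetype_dataset()` builds a landscape and point patterns
whose ground-truth rarity classes are known, one mechanism per axis:

- **Landcover**: nearest-seed Voronoi patches (default 10 classes,
  12 km patch scale, 4 km cells on a 500 km square domain), classes
  assigned to patches round-robin so all classes exist. Spatially
  autocorrelated, like a real landcover map; unlike one, patches have
  no size hierarchy or class imbalance.
- **Range**: points live within `range_radius_km` of a uniformly drawn
  centre — 20 km for Narrow archetypes, 170 km for Wide.
- **Abundance**: Thomas-process-style clustering. Large-abundance
  archetypes use 8 parent clusters with offspring sd 1.0 km (tight
  clusters compress nearest-neighbour distances, inflating
  $D_{\max}/D_{\min}$); Small-abundance archetypes use 12 clusters with
  sd $0.35 \times$ radius (diffuse). Offspring offsets are Gaussian
  truncated at 4 sd, which turns the bound
  $D_{\max} \le 2(\text{radius} + 4\,\text{sd})$ from a probabilistic
  statement into a deterministic guarantee the tests can assert.
- **Specificity**: Restricted archetypes may occupy 2 of the 10
  classes, Broad all 10, enforced by rejection sampling (capped at
  1000 tries per point). Cluster parents of restricted species are
  themselves resampled onto allowed habitat — a habitat specialist's
  local populations sit in its habitat — without which tight-cluster
  restricted archetypes cannot place points at all.

Coordinates are planar km: at ≤ 500 km extents geodesy adds nothing,
and the lonlat code path is exercised separately by small hand-made
fixtures. All generators are pure functions of (parameters, seed) with
the RNG kind pinned, so outputs are bit-identical across runs and
platforms.

These defaults were fixed after a single calibration run targeting
realized index ranges of the same order as a national flora analysis
($D_{\max}$ up to ~500 km, abundance ratios ~10–400, specificity 1–10)
and have not been revisited. The calibration's one substantive lesson:
most abundance-axis misclassifications are Large-abundance species
whose few parent clusters happen to land close together, shrinking
realized $D_{\max}$; 8 clusters rather than 4 stabilizes it. On this
stated world the full pipeline recovers archetype labels with overall
accuracy 0.79–0.88 and per-axis accuracy ≥ 0.85 across seeds 1–5
(8 archetypes × 25 species), against chance levels of 0.125 and 0.5.

What a green recovery test does *not* establish: robustness to survey
bias (transect sampling, detection probability, spatial effort
gradients), to taxonomic noise, or to the heavy right-skew of real
range-size distributions. The generator emulates the statistical
structure the indices respond to, not the survey process.

## Numerical and degenerate-input choices

- Haversine arcsine argument clamped at 1 to avoid NaN on antipodal
  rounding; Earth radius fixed at the IUGG mean radius.
- `D_min` uses the exhaustive $O(n^2)$ neighbour search; per-species
  $n$ is small and the brute-force result is the test oracle's
  definition, so no spatial index is used.
- Collinear point sets have hull area 0; fewer than 3 unique points
  give `NA` and such species are excluded from the hull-agreement rate.
- Fewer than 2 unique points is a hard "degenerate species" error for
  the distance metrics; the metrics driver filters those species out
  with a warning instead of erroring.
- Grid row/column counts use ceiling division so the grid always covers
  the extent; a zero-span extent yields a 1 × 1 grid.
- Empty narrow or wide group under `within_group` cutoffs is an error
  that names `global` mode as the fallback, not a silent mode switch.

## Limitations

- The minimum-records filter (default 2) keeps coverage high but lets
  two-record species into the narrowest classes, which inflates
  `N/R/S`-type counts in real surveys; the classification CSV carries
  `n_obs` so users can stratify.
- The abundance ratio is a proxy; with true abundance records it should
  not be used.
- Habitat specificity inherits both survey-point and landcover-map
  error, and a landcover class count is not a niche-breadth
  measurement.
- Mean-based cutoffs are sensitive to the right-skew of $D_{\max}$ and
  abundance distributions; both cutoff modes are provided but no
  robust-statistic alternative is implemented.
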