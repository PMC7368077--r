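---
title: "Methods: spatial null models and tiered coverage for protected-area gap assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial null models and tiered coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protgap)
```

## The question

A protected-area network can cover a large share of a country while still
missing the species that most need it. `protgap` asks two questions of any
network of highly protected areas (GAP status 1–2 in PAD-US terms) and a
set of endangered-species range maps:

1. **Is the network placed any better than chance?** For each ecoregion,
   the observed number of unique endangered species whose ranges overlap
   its protected areas is compared with the distribution of that count
   under random re-placement of the same protected areas within the same
   ecoregion.
2. **How far down the land-tenure cascade must protection extend before
   each species reaches adequate coverage?** Each species' range is
   apportioned across an ordered sequence of land designations, and the
   cumulative percentage is compared with a 30% adequacy threshold.

## The null model

Within an ecoregion holding protected-area parts $P_1,\dots,P_k$ and
species ranges $R_1,\dots,R_S$, the observed statistic is the count of
unique species

$$ N_{\mathrm{obs}} \;=\; \bigl|\{\, s : \operatorname{area}(R_s \cap
   \textstyle\bigcup_i P_i) > \varepsilon \,\}\bigr|, \qquad
   \varepsilon = 10^{-6}\ \mathrm{km}^2 , $$

so edge touches never count and a species overlapping several parts counts
once. Each null draw re-places every part independently by a **uniform
rigid motion**: a rotation $\theta \sim \mathrm{U}[0, 2\pi)$ about the
part's centroid followed by translation of the centroid to a point drawn
uniformly from the ecoregion's interior. Placements must be fully
contained in the ecoregion (`containment = 1`, adjustable); a part for
which rejection sampling fails `max_tries` times falls back to the
best-contained candidate clipped to the ecoregion, and the fallback is
counted and reported. Placed parts may overlap one another — leaving
overlap unconstrained makes the observed network, where overlap is
impossible, look conservative rather than flattering. The comparison point
is the **mean** of the null counts, and an ecoregion is classified
`better` / `worse` only when
$|N_{\mathrm{obs}} - \bar N_{\mathrm{null}}| \ge 1$ species (inclusive
boundary); everything inside the margin is `equal`.

Reproducibility: all draws come from R's RNG, and each ecoregion uses a
substream seeded deterministically from (master seed, ecoregion id), so
results are identical across runs and independent of evaluation order.

### Preprocessing rules

- Only GAP status 1–2 units enter the analysis (`select_protected`).
- Units with area **strictly below 5 km²** are removed; a unit of exactly
  5 km² is retained (`filter_min_area`). The size filter is applied to
  whole units *before* ecoregion splitting, so post-split parts may be
  smaller than the cutoff; the opposite order would silently delete small
  cross-boundary slivers of large reserves.
- Units spanning several ecoregions are split into parts clipped to each
  ecoregion (`split_by_ecoregion`); parts below the 1 m² sliver tolerance
  are dropped. Adjacent units are deliberately **not** dissolved first:
  each database feature is one unit.
- Species ranges are dissolved to one multipolygon per species, clipped to
  the study boundary, and the clipped area becomes the denominator of all
  later percentages (`normalize_ranges`).

## The tier cascade

`build_tier_map` partitions the study area into mutually exclusive tiers
in a fixed precedence order:

`PROTECTED_GAP12 → EASEMENT → USFS_BLM → OTHER_FEDERAL → STATE →
PRIVATE_UNDEVELOPED → PRIVATE_OTHER`

Every location belongs to the *first* tier whose source layer covers it, so
a USFS parcel inside a GAP-2 reserve counts as protected, and an easement
over state land counts as state. Private land is the remainder after all
public and protected layers are removed (`private_mask`), and is split on
the landcover grid: cells whose code is any "developed" class or
"cultivated crops" are excluded, the rest are undeveloped private land.
Cell membership is decided by the **cell centre** — unbiased for area in
expectation and exactly reproducible. The undeveloped-private percentage of
a range is therefore a raster quantity with discretisation error bounded by
(range perimeter × cell size)/range area, while all higher tiers are exact
vector overlays; the `PRIVATE_OTHER` percentage is defined as the vector
private percentage minus the raster undeveloped percentage, so each
species' tier percentages sum to exactly 100.

A species is **adequately protected** through tier $t$ when its cumulative
percentage at $t$ reaches the threshold; the default is 30%, inclusive
(exactly 30.0% counts), a rule-of-thumb persistence target used in place of
species-specific population viability analysis. `count_adequate` is
non-decreasing along the cascade by construction.

## Geometry engine

No polygon-overlay library is assumed: the package carries its own planar
engine (`src/geometry.cpp`) in which every geometry is a list of convex
rings with pairwise disjoint interiors. Simple rings (optionally with
holes) enter via ear-clipping triangulation; self-intersecting rings are
repaired by noding and loop extraction (a bow-tie becomes its two lobes).
Intersection of convex pieces is Sutherland–Hodgman clipping; difference of
two convex pieces is a fan of convex pieces; unions are built by
subtracting the accumulated union from each incoming part. All areas are
then exact sums of shoelace areas — overlay area is conserved to floating
point, which the tests assert directly. Degenerate (zero-length) edges are
removed after every clip; pieces below 10⁻⁹ m² are dropped.

Coordinates are metres in a single planar equal-area CRS. Synthetic worlds
declare a local Cartesian CRS; geographic (longitude/latitude) input is
projected with a built-in spherical Albers equal-area conic whose
equal-area property is tested against an independent geodesic area
computation on the same sphere. Vector I/O is GeoJSON; rasters use the
plain-text ESRI ASCII Grid format, which carries no CRS, so readers must
state one explicitly.

## The synthetic-world generator

The generator emulates the statistical structure the analysis assumes —
an ecoregion partition, clustered species ranges, a protected-area network
with controllable placement bias, a tenure tessellation, and a categorical
landcover grid — with exact per-species ground truth, so the whole pipeline
is testable with no external data.

- **Ecoregions** are Voronoi cells grown around random sites: contiguous,
  non-overlapping, covering the extent exactly.
- **Ranges** are star-shaped blobs (a disc whose radius is perturbed by
  low-order harmonics, guaranteeing simple polygons), with log-normal
  areas (median 80 km², log-sd 0.8). 90% of range centres scatter
  (sd 3.5 km) around richness hotspots, one per ecoregion; the rest are
  uniform. Endangered-species richness is strongly clustered in real
  landscapes, and the classification margin is an *absolute* one-species
  difference, so a generator without hotspot structure cannot express
  placement bias at all: the default world is deliberately rich
  (96 species) for the same reason.
- **Protected areas** (30, log-normal median 12 km², truncated at the
  5 km² analysis cutoff so the generated network equals the analysed one)
  are allocated to ecoregions proportionally to area with a minimum of 3
  per ecoregion, so the null comparison is informative in every stratum.
  At `bias_beta = 0` each is placed by *the same rigid-placement sampler
  the null model uses* — the observed layout is then one draw from the
  null by construction, which makes the calibration test exact. With
  `bias_beta` ≠ 0, centroids are drawn from a density proportional to
  $\exp(-\beta R(x))$, where $R(x)$ is the number of ranges covering $x$,
  evaluated on a fine in-ecoregion lattice with within-cell jitter.
- **Tiers** label the cells of a fine Voronoi tessellation of
  non-protected land (largest-deficit-first) to hit configured proportions
  within about one tile (~2 percentage points); **landcover** assigns
  developed (p = 0.10) and cultivated-crops (p = 0.25) cells on private
  land, NLCD-style codes {21, 82} in a three-code toy legend.
- **Truth** is computed at generation time from the generator's own
  labelled layers by exact overlay, using the same cell-centre rule for
  the raster tier; the pipeline's tier assembly, mask derivation and
  cascade bookkeeping are computed independently of it.

What passing tests do *not* show about real data: the generator has convex
ecoregions, simply-shaped ranges, no spatial autocorrelation in landcover,
no range–habitat cohesion, and tenure fractions far from the real USA's;
conclusions about a real network require the real layers.

## Numerical and design choices

- Sliver tolerance 1 m² wherever overlay residue is dropped; tier
  exclusivity and coverage invariants are asserted at 0.01% of the study
  area.
- The species-counting epsilon (1 m²) makes "touching along an edge" a
  non-overlap; any positive-area overlap above noise counts.
- Containment semantics for re-placement ("within its ecoregion") default
  to full containment with a clip-to-ecoregion fallback after 100 failed
  tries — the observed parts are themselves clipped to ecoregions, so the
  fallback mirrors the observed layout; partial-overhang nulls are
  available through `containment < 1`.
- The ±1-species margin is inclusive on both sides; the mean (not median)
  of null counts is the comparison point.
- The 30% threshold is inclusive (`inclusive = FALSE` switches to a strict
  reading).
- Test and acceptance runs use scaled problem sizes — 200 synthetic
  ecoregions at 250 iterations for calibration, 80 per bias sign, a
  100 × 100 km default world — chosen so the full suite completes in
  minutes while keeping standard errors far below the margins being
  tested. Calibration replicates are single-ecoregion worlds: ecoregions
  within one world share species ranges, so their classifications are
  correlated and would overdisperse the better/worse symmetry test;
  independent worlds make the binomial reference distribution exact.

## Known limitations

- Overlay complexity is quadratic in convex-piece counts per bounding-box
  bucket; national-scale layers (10⁵+ features) would need a stronger
  spatial index than the built-in bbox buckets.
- GeoJSON and ASCII Grid are the only I/O formats; there is no Shapefile,
  GeoPackage or GeoTIFF reader.
- The Albers projection is spherical; ellipsoidal (geodesic) areas are out
  of scope, and differences from spherical areas (~0.1–0.3%) exceed the
  package's internal overlay tolerances.
- The null model treats ecoregions independently and ignores cross-
  boundary placements, spatial autocorrelation corrections, and seasonal
  or corridor-based range structure.
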