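---
title: "Methods: phytoindication, hemeroby and divisive classification of relevé data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phytoindication, hemeroby and divisive classification of relevé data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoind)
```

## Scope and model of the data

`phytoind` analyses relevé data — plot × species tables of projective cover
(% of plot area) collected on fixed quadrats (default 4 × 4 m) — together
with a species indicator-value table. Covers live in (0, 100]; absences are
never stored, and summed plot cover may exceed 100% in layered vegetation
(no renormalization at ingest). Braun-Blanquet cover-abundance codes are
accepted at ingest and converted through fixed midpoints
(r → 0.1, + → 0.5, 1 → 2.5, 2 → 15, 3 → 37.5, 4 → 62.5, 5 → 87.5); the
midpoint convention is a package decision, made because cover coding
practice varies between surveys and the analysis downstream only sees
percentages.

Species matching everywhere is exact after whitespace/case normalization.
Fuzzy or synonym matching is deliberately excluded: a silently mis-matched
taxon corrupts community indicator means in a way no downstream check can
catch. Unmatched names are reported, never dropped quietly.

## Phytoindication

A plot's community score on an ordinal indicator scale is the mean score of
its species on that scale. The default aggregation is the unweighted
(presence-based) arithmetic mean, the classical choice in phytoindication;
cover weighting (`Σ cᵢ sᵢ / Σ cᵢ`) is a switch because surveys differ in
how reliably cover is estimated. A score is only reported when at least
`min_species = 3` species carry a value on the scale — one or two species
do not constitute a community signal; the threshold is configurable.

Twelve published conversions turn community scores into physical
quantities:

| factor | conversion | output |
|---|---|---|
| Hd (soil humidity, 23 grades) | `W = 18.65·e^(0.15·Hd)` | productive moisture, mm in the 1-m layer |
| fH (moisture variability, 12) | `ω = 0.042·fH − 0.032` | irregularity coefficient, 0–0.5 |
| Ae (aeration, 15) | `P = (100 − Ae⁴)/(100·(Ae⁴ + 1700))` | air-filled porosity (formula output) |
| Rc (acidity, 15) | `pH = 2.26·ln(Rc) + 1.88` | soil-solution pH |
| Sl (salt regime, 19) | `S = 2^(0.6·Sl + 1)` | salt content, µg/l |
| Ca (carbonates, 13) | `CaO+MgO = 14·Ca⁴·⁵/(Ca⁴·⁵ + 45000)` | carbonate content, % |
| Nt (nitrogen, 11) | `N = 5·Nt³·⁷/(Nt³·⁷ + 345)` | soil nitrogen, g/kg |
| Tm (thermal regime, 17) | `RB = 0.21·Tm` | radiation balance, gJ m⁻² yr⁻¹ |
| Om (ombroregime, 23) | `Hum = 0.54·Om − 7` | precipitation − evaporation, mm/day |
| Kn (continentality, 17) | `SKn = 10·Kn + 41` | Ivanov continentality scale |
| Cr (cryoregime, 15) | `Temp = 3.83·Cr − 38.17` | coldest-month mean, °C |
| Lc / Ellenberg L | `log_lighting = 0.22·L` | decimal log of relative light |

Each formula is implemented exactly as published, with no post-hoc
rescaling. Two numerical caveats are deliberate:

* the aeration output is ~6×10⁻⁴ at `Ae = 1`, implausible as a literal
  percentage; the value is reported as formula output and documented as
  such rather than "corrected";
* `ω` is not clipped to [0, 0.5] — at the scale maximum `fH = 12` the
  formula yields 0.472, inside the stated range anyway.

Conversions are mathematically defined for any positive score, so
out-of-range inputs are converted but flagged; `Rc ≤ 0` is a hard domain
error (logarithm). Productive moisture classifies into agronomic supply
classes at 60/90/130/160 mm. The published class descriptions overlap at
the bin edges, so the package fixes lower-inclusive half-open intervals:
exactly 130 mm is "good".

The light conversion is attributed in the source literature to the
Ellenberg L-value while the companion edaphic factors are Didukh scales;
`plot_regimes(..., light_scale =)` lets either column feed it, with the
Didukh `Lc` as default for internal consistency of the factor set. Other
Ellenberg factors have no published conversion here and are reported on
their native ordinal scales.

## Hemeroby and naturalness

Hemeroby grades species on a 7-step ordinal scale of anthropogenic
transformation (1 ahemerobic … 7 metahemerobic). The plot **hemeroby
index** is the community-weighted mean grade (cover weighting by default —
the standard operationalization); the **naturalness index** is the share of
contributing weight carried by species of grade ≤ 3
(ahemerobic–mesohemerobic; `natural_threshold` configurable 1–6). The pair
is intentionally not a mirror image (`naturalness ≠ 8 − hemeroby`): a
uniformly mesohemerobic stand and a mix of pristine and artificial elements
can share a mean grade yet differ sharply in naturalness, which is exactly
the distinction the two indices are meant to carry when both enter an
ordination. Which published grade list is assigned to species is left to
the user's indicator table; the format is agnostic to the source.

## TWINSPAN-style classification

Classification follows the two-way indicator species analysis scheme:

1. species are expanded into binary **pseudospecies** at cover cut levels
   0, 2, 5, 10, 20% (nested: cover 7% switches on cuts 0, 2 and 5);
2. at each node the first correspondence-analysis axis is extracted by
   **reciprocal averaging** (power iteration with the trivial solution
   deflated each step; tolerance 1e-10, cap 10⁴ iterations — the axis-1
   eigenvalue matches a dense eigensolver to better than 1e-8 in tests);
3. plots split at the axis centroid (weighted mean score, which is 0 by
   construction); a plot exactly at the centroid goes to the negative side,
   a fixed rule that makes the partition deterministic;
4. up to 5 indicator pseudospecies maximizing the between-side indicator
   value are recorded for each division;
5. division stops at `max_levels = 6`, when a side would fall below
   `min_group = 5` plots, or when the node has no compositional signal.

One departure from the original algorithm is documented rather than
hidden: the recorded indicator pseudospecies *characterize* each division
but the final allocation is the ordination split itself; the
misclassification-repair pass of the original procedure is omitted.
Desktop TWINSPAN implementations differ in undocumented details at exactly
this point, so the package targets partition-level agreement (measured by
the adjusted Rand index against known labels), not label-by-label
replication of any one program. Defaults (6 levels, minimum group 5) make
12 terminal groups reachable from 135 plots, matching the size of survey
the tool is intended for. `twinspan_groups(tree, k)` cuts the hierarchy to
`k` groups by replaying divisions in decreasing-eigenvalue order — the
strongest compositional splits first — which is how a fixed number of
vegetation units is usually read off a divisive tree.

**Fidelity.** Diagnostic species are found with the phi coefficient on the
2×2 occurrence table, `φ = (N·n_p − n·N_p)/√(n·N_p·(N−n)·(N−N_p))`, with
group sizes equalized beforehand to a virtual design where the target group
holds half the plots (removing the dependence of φ on unequal group
sizes); significance comes from a two-sided Fisher exact test on the *raw*
table — the customary companion of φ in synoptic-table practice, chosen
here because no particular test is mandated by the method itself. A species
is flagged diagnostic for its best group when `p < 0.05` **and**
`φ ≥ 0.25` (both configurable). A species present in every plot has φ = 0
by convention; other degenerate denominators yield a missing φ.

## Ordination

`pca_environment()` performs correlation-matrix PCA (variables
standardized with the n−1 denominator): the per-plot block mixes ordinal
scores with indices on disparate scales, and correlation PCA keeps loadings
interpretable as variable–component correlations bounded by ±1. Components
with eigenvalue > 1 are retained (Kaiser). Each component's sign is fixed
so its largest-|loading| variable loads positive, making outputs
reproducible. Loading significance uses the correlation t-test,
`t = r·√((n−2)/(1−r²))` on n−2 degrees of freedom, and masked tables render
non-significant cells empty. Group-wise means ± sample SD are provided by
`summarize_by_group()`; post-hoc multiple-comparison machinery (Tukey,
Dunn, compact letters) is ordinary library statistics and out of scope.

## Water-body morphometry

A terrain grid (ESRI ASCII raster; the package reads and writes the format
directly since it is plain text) is inundated at a water-surface
elevation: a cell is water when its elevation is *strictly below* the
level — a deterministic boundary rule, so a level exactly at the minimum
elevation yields an empty water body. Bodies are labeled with
8-connectivity (diagonal channels connect); nodata cells are never water
and generate shoreline. Measures per level: area = cell count × cell area;
volume = summed depth × cell area; shoreline = count of water-cell edges
facing dry/nodata/border × cell size. Cell-edge shorelines are biased
upward relative to vector shorelines (a known property of grid perimeters)
but are exactly testable against per-cell enumeration, which the tests do;
consequently *changes* between scenarios are the intended product, not
absolute shoreline lengths. `change_table()` computes percent decreases
`(from − to)/from × 100`, rounded half-up to one decimal, between named
scenarios.

## The synthetic generator

`community_scenario()` fixes the study conditions: 12 associations spread
along a dominant latent moisture gradient (with decorrelated trophic and
light gradients), 146 species in association pools, 135 plots, per-plot
richness N(12.1, 4.6²) truncated to [5, 28], per-species covers lognormal
(meanlog 0.94, sdlog 1 — meanlog derives from the target mean total cover
≈ 50.8% at mean richness 12.1: `log(50.8/12.1) − ½·1²`), truncated to
(0, 100] by redrawing, never renormalized. Dry associations receive high
hemeroby locations (`1 + 6·(1 − moisture)`), emulating ruderal colonization
of drawdown substrates; the coupling is on by default so hemeroby and
naturalness recovery have signal, and can be switched off to produce a
null community. Three species per association sit exactly at the
association optimum as planted diagnostic species. Everything is
deterministic given a seed (Mersenne-Twister).

What the generator does *not* emulate: spatial autocorrelation between
neighbouring plots, temporal succession, species abundance asymmetries
(dominants vs. satellites within a pool), observation error in cover
estimates, and nested syntaxonomic structure. Passing recovery tests
therefore demonstrate that the pipeline's machinery recovers planted
structure of realistic size and noise — not that any particular field
classification is correct.

Problem sizes used in the shipped tests and the acceptance script — 135
plots, 146 species, 10 generator seeds for the diagnostic-recovery rate,
50×50 random grids and a 60×60 paraboloid basin for morphometry — were
chosen as the smallest sizes at which the planted structure is
unambiguous.

## Numerical choices and degenerate inputs

* Reciprocal averaging starts from a deterministic vector (column-index
  averages) and fixes the score sign by the first nonzero coordinate, so
  results do not depend on RNG state; a node whose deflated start vector is
  ~0 (e.g. all plots identical) reports eigenvalue 0 and becomes a leaf.
* Completely disjoint species blocks drive the CA eigenvalue to exactly 1;
  the implementation accepts this boundary value.
* A plot with zero pseudospecies is a hard error before division — it
  cannot be placed by composition.
* `round_half_up()` exists because base `round()` is round-half-even and
  published percentage tables are conventionally half-up.
* Missing indicator scores are empty cells throughout; 0 is out of range on
  every scale and never a sentinel.

## Known limitations

* TWINSPAN here omits the misclassification-repair pass (above); trees from
  other implementations may disagree near division boundaries.
* Absolute shoreline lengths inherit the grid-perimeter bias; compare
  scenarios, not absolute values, across data sources.
* The aeration conversion is reported verbatim despite its implausible
  magnitude as a percentage.
* PCA drops plots with any missing variable; with `min_species` filtering,
  sparse surveys can lose plots — inspect `dropped_plots`.
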