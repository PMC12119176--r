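---
title: "Realized-niche envelopes and suitability scoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Realized-niche envelopes and suitability scoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelpniche)
```

## The problem and the model

Kelp restoration, protection and farming projects fail when the chosen site
lies outside the environmental conditions the target species can tolerate.
`kelpniche` characterizes those conditions empirically: instead of fitting a
species distribution model — problematic with presence-only archives, and
opaque because a composite suitability index hides the individual variables —
it reports, for each species in each marine ecoregion, the **envelope of the
conditions under which the species has actually been observed**.

For a set of occurrence records of species $s$ assigned to ecoregion $e$,
with $v_1, \dots, v_n$ the values of one environmental variable extracted at
the record locations (non-missing only), the envelope row is

$$(\min v,\; Q_{0.25}(v),\; \bar v,\; Q_{0.75}(v),\; \max v,\; n).$$

The quantile is the linear-interpolation definition: with sorted values
$x_{(1)} \le \dots \le x_{(n)}$ and $h = (n-1)p + 1$,

$$Q_p = x_{(\lfloor h \rfloor)} + (h - \lfloor h \rfloor)\,
        (x_{(\lfloor h \rfloor + 1)} - x_{(\lfloor h \rfloor)}),$$

i.e. R's default type 7 — deliberately, so the tables match what a plain
`dplyr::summarise()` over the same records produces. Ecoregions are the
summarization stratum because a species' realized niche varies regionally
with genetic and phenotypic structure; a single global envelope would blur
exactly the variation a practitioner in one region needs.

The interpretation rests on the bell-curve niche assumption: an optimum in
the middle of the observed range, less preferred conditions towards the
observed extremes, intolerable conditions beyond them. Under it, the
interquartile band $[Q_{0.25}, Q_{0.75}]$ approximates the "optimal"
conditions and $[\min, \max]$ the tolerated ones.

## Pipeline stages and their contracts

1. **Ingestion** (`read_occurrences()`): delimited text with a header
   (comma/tab autodetected), GBIF simple-download column names by default.
   Rows with unparseable or out-of-range coordinates, or a blank species
   name, are never silently dropped: each goes to a rejection log with a
   reason code, and `records + rejections = rows` is asserted by tests at
   every stage that drops rows. Records without a year are kept — the year is
   provenance, not a filter. Exact-duplicate dropping exists but defaults to
   off: envelopes are defined over raw observations, and the archive's
   duplicates carry abundance signal that deduplication would erase.
2. **Taxon filter** (`filter_taxon()`): case-insensitive match on the order
   column (kelps: Laminariales).
3. **Land removal** (`drop_land_points()`): a record whose location has no
   value on a designated reference ocean layer is treated as land-based or
   out-of-domain and logged. This operationalizes "remove land observations"
   without a separate landmask input; a polygon-based mask can be emulated by
   supplying a rasterized ocean layer.
4. **Extraction** (`extract_at_points()`): containing-cell lookup, no
   interpolation. Cell $(r, c)$ (row 1 northmost) covers
   $[\mathrm{west} + (c-1)\,dx,\ \mathrm{west} + c\,dx)$ in longitude and
   $(\mathrm{north} - r\,dy,\ \mathrm{north} - (r-1)\,dy]$ in latitude — the
   half-open convention stated once and used everywhere (extraction,
   resampling, zonal membership), so edge points belong to exactly one cell.
   Bilinear interpolation is deliberately avoided: near coasts it would
   manufacture values from land-adjacent nodata. Each variable is extracted
   at its native resolution, independently — a record on a coastal nodata
   cell of one layer still informs the others.
5. **Ecoregion assignment** (`assign_ecoregions()`): even-odd point-in-polygon
   containment; a point on a shared boundary goes to the smaller `eco_id`
   (deterministic, order-independent). `snap_tolerance` (default 0) can
   rescue records sitting just outside coastal polygons by snapping to the
   nearest boundary within that distance; it defaults to strict containment
   because snapping invents an assignment. Unassigned records are retained
   but excluded from all summaries — they have no stratum.
6. **Minimum-observation filter** (`filter_min_observations()`): only
   species–ecoregion pairs with **strictly more than** `threshold` records
   (default 10, i.e. $n \ge 11$) are summarized, taking the data-quality rule
   literally; a pair with exactly 10 records is dropped. The filter counts
   occurrence records per pair, before per-variable missing-value exclusion —
   so a surviving pair may report a per-variable `n_obs` at or below the
   threshold for a sparse layer; that is reported, not re-filtered, because
   the rule governs observations, not per-variable extractions.

## Suitability scoring

`recipe_from_summary()` turns an envelope row into a band recipe:
mode `"iqr"` sets the band to $[p25, p75]$ with $[\min, \max]$ as exclusion
bounds; mode `"range"` uses $[\min, \max]$ as the band. Band bounds are
inclusive at both ends — the natural reading of "between", and it keeps the
degenerate $p25 = p75$ band non-empty. `reclassify_band()` maps a layer to
1 inside the band, 0 outside; `graded = TRUE` gives the three-level 2/1/0
scheme (band / tolerated envelope / outside), the simplest faithful encoding
of "values nearer the optimum rank higher" — a continuous distance-to-mean
kernel is out of scope by design, as the tool reports observed ranges, not a
fitted response curve.

`stack_score()` computes $\mathrm{score} = \sum_i w_i\,b_i$ per cell. Layers
on other grids are resampled by nearest-cell lookup onto the finest input
grid (consistent with containing-cell extraction). Nodata propagates
conjunctively — a cell missing any evidence gets no score — because a partial
sum reads as a low score when it is actually ignorance; the `"lenient"`
policy instead rescales by the available weight, for users who prefer
coverage over strictness. With all weights 1 every score is an integer count
of in-band variables, and `max_score = sum(weights)` is attainable exactly
where every band is satisfied. `zonal_stats()` ranks polygons by mean score
(cell-center membership, ties to the smaller zone id), reporting cell counts,
the observed maximum and the fraction of cells at the attainable maximum.

## The synthetic study system

`synthetic_world()` is first-class, tested code, not a fixture dump. It
emulates the structure of the real inputs at desk scale: an 80 × 80
quarter-degree grid with 15% of cells as land under one shared mask; a
west–east sea-surface-temperature ramp (8–22 °C) plus smooth random salinity
(31–36 PSS) and nitrate (2–20 µmol/L) fields; four equal-width strip
ecoregions; three kelp species with Gaussian niches of distinct breadth and
strongly skewed sample sizes (1200 / 400 / 80 records — real occurrence
archives are dominated by a few heavily-sampled regions and taxa), plus a
60-record species of a different order that the taxon filter must remove.
Occurrence sampling realizes the bell-curve assumption directly: cells are
drawn with probability proportional to the product over variables of the
Gaussian density of the cell's value (independent variables, no covariance
structure — a deliberate simplification), and points sit at cell centers so
extraction recovers the generating value exactly; a jitter option exercises
boundary handling. All generators are seed-deterministic.

What passing tests on this world do **not** show about real data: no spatial
autocorrelation of sampling effort, no coordinate error, no taxonomic
synonymy, no temporal mismatch between observation dates and layer epochs
(present in real archives and not corrected here), and rectangular rather
than coastline-shaped ecoregions.

## Numerical and design choices

* **Cell lookup robustness.** The candidate index from `floor()` division is
  verified against the defining containment inequalities (and its neighbours
  tried) so lookup agrees exactly with a literal scan even when floating-point
  division rounds across a cell edge.
* **Quantiles** delegate to `stats::quantile(type = 7)`; the test suite
  checks them against an independent transcription of the formula on 200
  random samples.
* **Point-in-polygon** uses the even-odd rule (holes supported). Rings that
  self-intersect are detected by a segment-pair scan and flagged; membership
  then follows the even-odd interpretation, which for point lookup matches
  what a zero-width-buffer repair of the ring would give. Antimeridian
  longitudes (±180°) are normalized to [−180, 180) before any lookup.
* **Formats.** Grids are single-band ESRI ASCII (values written at full
  double precision, so write/read round trips are exact); polygons are
  GeoJSON; tables are CSV with JSON metadata sidecars. These plain-text
  formats keep every artifact diffable and the round-trip tests exact.
* **Determinism.** All randomness flows from one configuration seed;
  `run_pipeline()` writes no timestamps into tables, making runs
  bit-reproducible (and tested as such).
* **Degenerate inputs.** Empty samples are a quantile domain error; an
  all-missing variable emits no envelope row; a niche spec with zero
  probability everywhere is a degenerate-spec error; empty zones report
  `n_cells = 0` with missing statistics; a header-only occurrence file is an
  empty set, not an error.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on generated data:
the default world (6,400 cells, 1,740 records), random grids up to 50 × 50
for the extraction oracle, 40 × 40 stacks for the scoring oracle, and a
5,000-record Gaussian-niche recovery on a 3,001-cell ramp, where the
recovered $p25$ and $p75$ are required to sit within three standard errors of
$\mu \mp 0.6745\,\sigma$ (the asymptotic standard error of a sample quantile,
$\sqrt{p(1-p)/n}\,/\,f(Q_p)$). These sizes give the property tests enough
resolution to fail on real defects while keeping a full run in seconds.

## Known limitations

GeoTIFF and shapefile inputs are not read directly — convert to ESRI ASCII /
GeoJSON first. All inputs are assumed geographic WGS84; there is no
reprojection. No taxonomic-backbone resolution, no coordinate-uncertainty
filtering, no correction for sampling bias: the envelopes describe the
archive, and inherit its biases — which is why the record-distribution
report (`report_record_distribution()`) quantifies the skew (records per
ecoregion and genus, top-k ecoregion share) alongside every run.
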