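---
title: "Methods: urban-constrained dasymetric population projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urban-constrained dasymetric population projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dasypop)
```

## The model

`dasypop` projects a gridded population annually by alternating two
deterministic steps under country-level scenario constraints.

**Ranking.** Fine pixels (30 arc-seconds in the intended application,
`1/120`°) nest `R × R` inside coarse cells (`R = 60` gives 0.5° cells).
Each year, every coarse cell's pixels are ranked by their current
population value and the top `k = round(f·R²)` are classified urban,
where `f ∈ [0, 1]` is the cell's urban fraction for that year. The
rationale is dasymetric: the most populated pixels of a cell are the
ones most plausibly covered by the cell's urban land.

**Allotment.** Countries partition the land pixels; the urban mask splits
each country into an urban and a rural stratum. A country with scenario
total `T(t)` and urban share `s(t)` distributes `s·T` over its urban
stratum and `(1−s)·T` over its rural stratum, each proportionally to the
previous year's pixel values. Proportionality preserves within-stratum
pixel ratios, and each country's pixel sum equals its scenario total up
to floating-point accumulation — mass conservation is structural, not
approximate, which is why aggregating any output year back to countries
reproduces the input series with r² = 1.

The loop is seeded by the baseline year and thereafter self-referential:
year `t` ranks and weights by the year `t−1` output. Pixels may switch
stratum between years; a pixel's weight is its previous value regardless
of its previous stratum.

### Tie-free ranking

Raw population grids contain ties (notably zeros), so the baseline adds
two perturbation layers before the first ranking:

* inverse distance to the nearest road polyline, and
* inverse distance to the pixel's own coarse cell's population centre of
  gravity (the population-weighted mean of pixel centres; cells with zero
  population fall back to their geometric centre).

"Inverse distance" is taken as `v = 1/(d + δ)` with `δ` equal to one fine
cell size: the raw reciprocal diverges on pixels crossed by a road, while
the offset version is bounded, strictly order-reversing, and scaled to
the grid. Each layer is then affinely rescaled so that, over the whole
domain, its minimum is `1.0e-5` and its maximum `1.1e-5` people — large
enough to separate tied pixels, and at least four orders of magnitude
below any demographically meaningful pixel value. The rescaling is one
global map per layer, not per coarse cell, matching the construction of a
single continent-wide perturbation surface. After both layers are added,
any two pixels whose raw populations differ by more than
`max(inv_road) + max(inv_cog) ≤ 2.2e-5` keep their raw order. Exact ties
can still occur between pixels symmetric about both a road and their
cell's centre of gravity; these are broken deterministically by linear
pixel index, so the within-cell ranking is a strict total order and
identical inputs always give bit-identical masks. The perturbations are
added once, at baseline; later years inherit uniqueness from the
allotment arithmetic plus the index tie-break.

Distances are planar Euclidean in lon/lat degree space. This matches the
simple raster distance tooling customary for such ancillary layers but
overstates east–west distances away from the equator; since the layers
only order pixels within a 0.5° neighbourhood and are then crushed into a
1e-5 band, the distortion has no practical effect on outputs.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `fine_cell_size` | 1/120 | degrees | fine pixel size (30 arc-seconds) |
| `refinement` R | 60 | – | fine pixels per coarse cell side |
| perturbation `lo`, `hi` | 1.0e-5, 1.1e-5 | people | rescaled layer bounds |
| `δ` (inverse-distance offset) | one fine cell | degrees | bounds `1/d` at roads |
| nodata | −9999 | – | invalid-pixel sentinel in GeoTIFFs |
| years | 2000–2100 | – | annual projection span |

Scenario combinations are selected from the shipped 5 × 4 SSP–RCP
plausibility matrix: every pair with probability > 0 runs (15 of 20);
the probabilities are used for inclusion only, never as weights.

## Numerical choices

* **Rounding.** `k = round(f·R²)` rounds halves away from zero. R's
  `round()` rounds halves to even, which would silently change urban
  counts (e.g. `f·R² = 4.5` would give 4, not 5); the package uses an
  explicit `floor(x + 0.5)` form.
* **Round, then cap.** `k` is computed from the full `R²` cell area —
  the urban fraction refers to cell area, not land area — and then
  capped at the cell's land pixel count, so water is never urbanised.
* **Empty strata.** A stratum with zero previous population but a
  positive target receives the target uniformly (conserves mass,
  deterministic). A country whose mask leaves it with *no* pixels in one
  stratum has that stratum's target reassigned to the other stratum with
  a warning; dropping it would silently lose population.
* **Annualization.** Country series arrive at multi-year steps and are
  interpolated linearly in both total population and urban share;
  provided steps are reproduced exactly and extrapolation is refused.
* **Indexing.** Grids use R's native 1-based, inclusive-range indexing
  (`block_of` returns inclusive row/column ranges); coordinates follow
  the dominant GeoTIFF convention — north-up, row 1 northernmost, origin
  at the top-left pixel corner.
* **Alignment.** Coarse and fine grids must share an origin and integer
  refinement; rasters that do not align with the run geometry are
  resampled at load by nearest neighbour with a logged notice. A coarse
  cell is treated as valid if it contains at least one valid fine pixel.
* **Baseline year output.** The first published year is already an
  SSP-consistent redistribution (using the unique-population surface as
  weights), not the raw baseline, so *every* output year satisfies mass
  conservation against the scenario series.
* **Degenerate inputs** are errors, not silent repairs: empty road sets,
  all-identical distance layers, urban fractions outside `[0, 1]`,
  missing scenario years or countries, and geometry mismatches all fail
  before any output is written.

### Stability of the loop

With constant fractions and series, one year's output is a fixed point
as soon as the urban mask stabilises: once the mask repeats, each
stratum's weights already sum to its target, every scaling factor is 1,
and the grid reproduces itself. The mask is guaranteed stable when each
country's urban share exceeds its urban stratum's share of population
mass (urban pixels are then scaled up relative to rural ones and stay on
top of their cells' rankings). When the urban share is *below* the urban
mass share, ranks can cross and the mask can keep adjusting — this is a
genuine property of the method, visible in adversarial synthetic
configurations, not an implementation artefact. The package's tests pin
the fixed-point and scale-equivariance properties on configurations that
satisfy the stability condition.

## The synthetic world

`generate_world()` emulates all five real inputs: baseline population as
isotropic density bumps around randomly placed "city" centres over a low
uniform background, normalised so each country's sum equals its baseline
total exactly; countries as vertical bands tiling the land area (water
occupies the southernmost rows); a trunk road crossing all countries plus
one road linking each country's cluster centres; coarse urban fractions
proportional to each cell's share of peak population, trending upward by
a constant annual increment and clipped to `[0, 1]`; and country series
at five-year steps growing at per-country rates drawn from 1–3 % yr⁻¹,
with urban shares starting near 0.35 and rising 0.005 yr⁻¹ — magnitudes
chosen to resemble rapidly urbanising continental scenarios. Everything
is reproducible from a single seed.

The generator deliberately does *not* emulate irregular coastlines and
borders, sub-national heterogeneity in growth, road-network topology, or
any calibration to a real census product. Consequently, green tests
demonstrate the algorithmic guarantees (conservation, ratio preservation,
top-k correctness, determinism, format fidelity) — they do not validate
demographic realism of outputs on real inputs, which depends entirely on
the quality of the baseline raster and scenario data supplied.

Test problem sizes: most unit fixtures use single coarse cells of 2×2 to
6×6 pixels where properties can be enumerated by hand or brute force
(all `C(n, k)` subsets for the mask oracle); pipeline tests use 2 × 2
coarse cells at refinement 10 (400 pixels, three countries) over one
projected decade, the scale at which a full run takes well under a
second.

## Validation machinery

`aggregate_by_region()` is a zonal sum; `region_compare()` reports r²
and RMSE of aggregated versus reference totals. The default r² is
computed about the **one-to-one line** (`1 − SS_res/SS_tot` with
residuals to the reference), which is the right statistic for "is all
the population accounted for where it should be"; a regression-based
variant (`method = "regression"`, the squared correlation) is available
for comparisons against independent gridded products, whose totals are
not expected to match one-to-one. With fewer than two regions, or a
constant reference, r² is reported as missing with a note rather than a
number. `change_report()` pairs per-region changes between two years
with reference changes for the same one-to-one reading.

## File formats

Outputs are single-band GeoTIFFs with 32-bit IEEE float samples (FLT4S),
declared nodata −9999, and WGS84 geographic referencing, one file per
scenario combination and year (`ssp<ssp>_rcp<rcp>_<year>.tif`). The codec
is implemented in the package and intentionally minimal: uncompressed,
strip-organised, little-endian output; the reader additionally accepts
big-endian, multi-strip and integer-sample files but refuses multi-band,
tiled, compressed or non-georeferenced input. Roads and borders travel
as GeoJSON; scenario series and the plausibility matrix as CSV; run
configuration as a YAML key-value file in which every method constant
surfaces with its published default.

## Known limitations

* Planar degree-space distances (documented distortion, see above).
* Nearest-neighbour is the only regridding; area-weighted aggregation of
  misaligned urban fractions is out of scope.
* One format per vector input (GeoJSON); shapefiles must be converted
  upstream.
* The Fig.-1-style loop is deterministic; scenario uncertainty is
  represented only by the discrete SSP–RCP combination set, and the
  plausibility values themselves are taken as given input.
* Projected (non-geographic) coordinate systems are unsupported.
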