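# dasypop

Dasymetric downscaling of country-level population scenarios onto a fine
geographic grid, constrained by coarse urban-fraction projections.

## The problem

Earth-system and impact models need population as a gridded field, but the
standard 21st-century scenario inputs come at two incompatible scales:

* **SSPs** (Shared Socio-economic Pathways) publish *country-level* total
  population and urban share, annually interpolable to 2100;
* **RCPs** (Representative Concentration Pathways) publish *gridded* land-use
  projections, including the urban fraction of each 0.5° cell, but no people.

`dasypop` couples the two: starting from a fine baseline population raster
(30 arc-second pixels, 60 × 60 of which nest in each 0.5° cell), it
classifies pixels as urban or rural so that each coarse cell's urban pixel
count matches its RCP urban fraction, then distributes each country's SSP
urban and rural population over the corresponding pixel strata, and iterates
the two steps annually so each year's grid seeds the next year's ranking.

## The method

For a baseline population grid `P` (people per pixel, water masked out):

1. **Unique population.** Two tiny perturbation layers are added to `P` so
   pixels can be ranked without ties: the inverse distance to the nearest
   road and the inverse distance to the pixel's coarse-cell population
   centre of gravity, each affinely rescaled into `[1.0e-5, 1.1e-5]` people.
   The total perturbation is at most `2.2e-5`, so only pixels that were
   essentially tied can ever swap rank; growth is favoured near roads and
   population centres.
2. **Urban mask.** Within each coarse cell with urban fraction `f` and
   `R × R` fine pixels, the `k = round(f · R²)` highest-ranked pixels are
   marked urban (`k` capped at the cell's land pixel count; halves round
   away from zero).
3. **Allotment.** For each country with total `T` and urban share `s`, the
   urban population `sT` is distributed over the country's urban pixels
   proportionally to the previous grid values, and `(1 − s)T` likewise over
   its rural pixels — so within a (country × urban/rural) stratum, pixel
   ratios are preserved and country totals are conserved exactly.
4. **Loop.** Steps 2–3 repeat each year, ranking on the previous year's
   output; the perturbations enter only at baseline.

Runs cover the plausible SSP–RCP combinations, selected from a 5 × 4
plausibility matrix (shipped with the package); 15 of the 20 pairs have
positive probability — SSP1–RCP8.5, for instance, is excluded.

Because no continental input data ship with the package, a synthetic-world
generator (`generate_world()`) produces internally consistent miniature
inputs — clustered population, countries, roads, trending urban fractions,
scenario tables — on which the whole pipeline and its tests run.

## Worked example

```r
library(dasypop)

world  <- generate_world(synth_spec(seed = 7))      # 3 countries, 2x2 coarse cells
unique_pop <- baseline_unique_population(world$baseline, world$roads)
series <- annualize(world$series, years = 2000:2010)
run    <- project_scenario(unique_pop, world$fractions, world$countries,
                           series, 2000:2010)
summary(run)[1:4, ]
#>  year total_population urban_pixels max_rel_residual
#>  2000           375353          142      1.32698e-16
#>  2001           384025          142      1.30555e-16
#>  2002           392696          143      1.28479e-16
#>  2003           401368          146      1.26469e-16

agg <- aggregate_by_region(run$grids[["2005"]], world$countries)
agg
#>   region_id n_pixels population empty
#> 1         1      126  221989.59 FALSE
#> 2         2      108  118664.22 FALSE
#> 3         3      126   78057.53 FALSE

yr <- series[series$year == 2005, ]
region_compare(agg, data.frame(region_id = yr$country_id,
                               population = yr$total_population))
#> <validation_report> 3 regions (one_to_one)
#>   r2   = 1
#>   RMSE = 0 persons
```

The summary shows, per year, the grid total (which follows the interpolated
country series), the number of urban pixels (which grows with the trending
urban fractions), and the largest relative difference between any country's
pixel sum and its scenario total — at machine precision, because allotment
is exactly mass-conserving. Aggregating any year back to countries and
comparing with the input series puts every country on the one-to-one line:
r² = 1, RMSE ≈ 0.

A thin command-line wrapper is installed at `inst/cli/dasypop.R` with
subcommands `synth`, `project`, `mask` and `validate`; outputs are written
one GeoTIFF per scenario and year (`ssp<ssp>_rcp<rcp>_<year>.tif`, 32-bit
float samples, nodata −9999, WGS84 lon/lat).

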