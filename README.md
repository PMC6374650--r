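# rarityframe

Rabinowitz rarity classification of species from presence-only
occurrence records.

Large presence-only survey datasets (national inventories, GBIF,
herbarium records) record *where* species were seen but nothing about
abundance or habitat preference. `rarityframe` extracts all three axes
of the classic Rabinowitz rarity typology from such data using only
point geometry and a categorical landcover raster:

- **Geographic range** — `D_max`, the largest distance (km) between any
  pair of a species' occurrence points;
- **Local abundance** — `D_max / D_min`, where `D_min` is the mean,
  over points, of each point's distance to its nearest conspecific
  neighbour (dense local occurrences compress `D_min` and inflate the
  ratio);
- **Habitat specificity** — the number of distinct landcover classes the
  species' points fall in.

Each index is binarized at an arithmetic-mean cutoff (range over all
species; abundance and specificity within the narrow- and wide-range
groups separately, or globally via `mode = "global"`), giving the
2 × 2 × 2 classes `N/R/S` … `W/B/L`. Seven of the eight are forms of
rarity; `W/B/L` (wide range, broad habitat, large abundance) is
"common". Ties at a cutoff go to the non-rare side. The package also
grids species richness per class at configurable resolutions, selects
each class's top-20% richest occupied cells, and overlays them into a
congruence map whose high-level cells flag multi-rarity hotspots for
conservation prioritization.

Because the survey datasets this workflow targets are rarely
redistributable, the package ships a seeded synthetic generator
(`generate_archetype_dataset()`): Voronoi-patch landcover plus
habitat-constrained Thomas-process point patterns with known rarity
archetypes, so the full pipeline — and its label-recovery accuracy — is
testable offline.

## Worked example

```r
library(rarityframe)

sim <- generate_archetype_dataset(n_per_class = 5, seed = 42,
                                  extent_km = 300)
sim$dataset
#> <occ_dataset> 1680 records, 40 species, coord_mode=planar_km

metrics <- compute_all_metrics(sim$dataset, sim$landcover)
head(metrics[, c("species_id", "d_max_km", "d_min_km",
                 "abundance", "habitat_count")], 4)
#>   species_id d_max_km  d_min_km abundance habitat_count
#> 1   NBL_0001 36.94488 0.7209430  51.24521             6
#> 2   NBL_0002 33.46820 0.7044214  47.51162             5
#> 3   NBL_0003 34.31845 1.1110053  30.88955             5
#> 4   NBL_0004 30.74262 1.0533117  29.18663             4

cutoffs <- compute_cutoffs(metrics, mode = "within_group")
cutoffs
#> <cutoff_set> mode= within_group
#>   range:       D_max < 152.8046 km -> Narrow
#>   specificity: habitat < 3.904762 (narrow) / 5.473684 (wide) -> Restricted
#>   abundance:   ratio < 38.94558 (narrow) / 114.815 (wide) -> Small

result <- classify_species(metrics, cutoffs)
result
#> <rarity_classification> 40 species
#>    code count percent
#> 1 N/R/S     8    20.0
#> 2 N/R/L     3     7.5
#> 3 N/B/S     7    17.5
#> 4 N/B/L     3     7.5
#> 5 W/R/S     5    12.5
#> 6 W/R/L     4    10.0
#> 7 W/B/S     5    12.5
#> 8 W/B/L     5    12.5

recovery_report(sim$truth, result)
#> <recovery_report> n=40 overall accuracy=0.85
#>   per-axis: range=0.975 specificity=1 abundance=0.875
```

The metrics table reads directly: `NBL_0001` spans ~37 km (narrow),
occupies 6 landcover classes (broad) and its points sit ~0.7 km from
their nearest neighbours, giving an abundance ratio of 51 (large) —
class `N/B/L`, matching its generating archetype. The recovery report
compares every assignment against the generator's ground truth.

The `D_max` range classification can be sanity-checked against the
convex-hull (extent-of-occurrence) alternative for species with three
or more unique points:

```r
range_size_agreement(metrics)
#> [1] 0.95   (40 eligible species)
```

Richness mapping and hotspot congruence:

```r
spec <- build_grid(sim$extent, cell_size = 10)           # 10 km cells
tops <- lapply(rarity_codes(), function(cls) {
  ids <- result$assignments$species_id[result$assignments$code == cls]
  top_fraction_cells(richness_grid(sim$dataset, spec,
                                   species_subset = ids,
                                   subset_label = cls), q = 0.20)
})
summary <- congruence_area_summary(congruence_map(tops),
                                   cell_area_km2 = 100)
```

## Command line

```sh
rarityframe simulate --seed 42 --out sim/
rarityframe classify --occurrences sim/occurrences.csv \
    --landcover sim/landcover.asc --coord-mode planar_km --out cls/
rarityframe map --occurrences sim/occurrences.csv \
    --classification cls/classification.csv --resolution 10,25,50 \
    --out maps/
```

(`rarityframe` is `inst/cli/rarityframe`; after installation it lives at
`system.file("cli", "rarityframe", package = "rarityframe")`.)

## File formats

- Occurrences: CSV with header (`species,x,y[,date]`), UTF-8; column
  names configurable. Coordinate mode (`lonlat` degrees or `planar_km`)
  is always declared, never inferred.
- Landcover and count rasters: ESRI ASCII grid
  (`ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`).
- Species lists: plain text, one name per line, `#` comments.
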