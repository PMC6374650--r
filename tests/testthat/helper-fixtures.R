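# Small fixtures built in code at test time.

# 4x4 landcover fixture, origin (0,0), 1 km cells, classes {1,2,3} with a
# nodata hole at the north-east corner cell. Row 1 = southernmost.
fixture_landcover <- function() {
  m <- matrix(c(1L, 1L, 2L, 2L,
                1L, 1L, 2L, 2L,
                3L, 3L, 2L, 2L,
                3L, 3L, 2L, -9999L),
              nrow = 4, byrow = TRUE)
  landcover_grid(m, x0 = 0, y0 = 0, cell_size = 1, nodata = -9999L)
}

# Two planar species with hand-checkable metrics:
#   sp_a: (0,0),(1,0),(5,0)  -> D_max 5, D_min mean(1,1,4)=2, ratio 2.5
#   sp_b: (10,10),(13,14)    -> D_max = D_min = 5, ratio 1
fixture_toy_dataset <- function() {
  occurrence_dataset(
    data.frame(
      species_id = c("sp_a", "sp_a", "sp_a", "sp_b", "sp_b"),
      x = c(0, 1, 5, 10, 13),
      y = c(0, 0, 0, 10, 14)),
    coord_mode = "planar_km", source = "fixture")
}

write_tmp_csv <- function(df, ...) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, ...)
  path
}

# Minimal cutoff_set for direct assignment tests.
make_cutoffs <- function(range_km, spec_narrow, spec_wide,
                         ab_narrow, ab_wide, mode = "within_group") {
  structure(list(
    range_cutoff_km = range_km,
    abundance_cutoff = c(narrow = ab_narrow, wide = ab_wide),
    specificity_cutoff = c(narrow = spec_narrow, wide = spec_wide),
    mode = mode), class = "cutoff_set")
}
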