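# Gridded species richness, top-quantile cell selection, and the
# congruence overlay across rarity classes.

#' Gridded species richness
#'
#' Each cell's value is the number of distinct species (of the chosen
#' subset) with at least one record in the cell — never the record count.
#'
#' @param ds An `occ_dataset`. For lonlat data project to planar km
#'   first; km-resolution grids assume planar coordinates.
#' @param spec A [build_grid()] result.
#' @param species_subset Optional character vector of species ids; `NULL`
#'   uses all species.
#' @param subset_label Free-text label stored with the grid.
#' @return Object of class `richness_grid`: `spec`, integer matrix
#'   `counts` (row 1 = southernmost row), `subset_label`, `n_species`.
#' @export
richness_grid <- function(ds, spec, species_subset = NULL,
                          subset_label = "all") {
  stopifnot(inherits(ds, "occ_dataset"), inherits(spec, "grid_spec"))
  rec <- ds$records
  if (!is.null(species_subset)) {
    if (length(species_subset) == 0L) stop("species subset is empty")
    rec <- rec[rec$species_id %in% species_subset, , drop = FALSE]
  }
  cells <- assign_point_to_cell(rec$x, rec$y, spec)
  inside <- !is.na(cells$row)
  if (nrow(rec) > 0L && !any(inside))
    warning("all points fall outside the grid; richness is all zero")
  counts <- matrix(0L, spec$n_rows, spec$n_cols)
  if (any(inside)) {
    u <- unique(data.frame(sp = rec$species_id[inside],
                           row = cells$row[inside],
                           col = cells$col[inside]))
    tab <- table(factor(paste(u$row, u$col)))
    rc <- do.call(rbind, lapply(strsplit(names(tab), " "), as.integer))
    counts[rc] <- as.integer(tab)
  }
  structure(list(spec = spec, counts = counts,
                 subset_label = subset_label,
                 n_species = length(unique(rec$species_id))),
            class = "richness_grid")
}

#' @export
print.richness_grid <- function(x, ...) {
  cat("<richness_grid> '", x$subset_label, "': ", sum(x$counts > 0),
      " occupied cells, max richness ", max(x$counts), "\n", sep = "")
  invisible(x)
}

#' Write a richness or congruence grid as ESRI ASCII
#'
#' Empty cells are written as the nodata code so that downstream GIS
#' tools render only surveyed cells, mirroring how zero-survey cells are
#' blank on the maps.
#'
#' @param grid A `richness_grid` or `congruence_grid`.
#' @param path Output `.asc` path.
#' @param nodata Integer code for cells with value 0.
#' @return Invisibly, the path.
#' @export
write_count_grid <- function(grid, path, nodata = -9999L) {
  m <- if (inherits(grid, "richness_grid")) grid$counts else grid$levels
  spec <- grid$spec
  m[m == 0L] <- as.integer(nodata)
  write_ascii_grid(m, spec$x0, spec$y0, spec$cell_size, nodata, path)
}

#' Top-quantile richness cells
#'
#' Ranks the occupied cells (richness > 0) by value and keeps the highest
#' `ceiling(q * n_occupied)`; all ties at the boundary value are
#' included, so the set can be larger than the nominal count. The
#' quantile base is occupied cells, not all cells: unsurveyed empty cells
#' dominate any national grid and would otherwise swamp the quantile.
#'
#' @param grid A [richness_grid()].
#' @param q Fraction of occupied cells to keep (default 0.20).
#' @return Object of class `top_cell_set`: `spec`, `cells` (data.frame
#'   row, col, value), `q`, `threshold_value`, `n_occupied`.
#' @export
top_fraction_cells <- function(grid, q = 0.20) {
  stopifnot(inherits(grid, "richness_grid"), q > 0, q <= 1)
  occ <- which(grid$counts > 0L, arr.ind = TRUE)
  if (nrow(occ) == 0L) stop("no occupied cells in richness grid")
  vals <- grid$counts[occ]
  k <- ceiling(q * length(vals))
  threshold <- sort(vals, decreasing = TRUE)[k]
  keep <- vals >= threshold
  structure(list(
    spec = grid$spec,
    cells = data.frame(row = occ[keep, 1], col = occ[keep, 2],
                       value = vals[keep]),
    q = q, threshold_value = threshold, n_occupied = length(vals),
    subset_label = grid$subset_label),
    class = "top_cell_set")
}

#' Congruence of top-richness cell sets
#'
#' Overlays the top-quantile cell sets of several species groups: each
#' cell's level is the number of groups whose top set contains it. High
#' levels flag multi-rarity hotspots.
#'
#' @param top_sets List of [top_fraction_cells()] results sharing one
#'   grid specification.
#' @return Object of class `congruence_grid`: `spec`, integer matrix
#'   `levels`, `n_groups`.
#' @export
congruence_map <- function(top_sets) {
  stopifnot(is.list(top_sets), length(top_sets) >= 1L)
  spec <- top_sets[[1]]$spec
  for (ts in top_sets) {
    stopifnot(inherits(ts, "top_cell_set"))
    if (!grid_specs_equal(ts$spec, spec))
      stop("top-cell sets use different grid specifications")
  }
  levels <- matrix(0L, spec$n_rows, spec$n_cols)
  for (ts in top_sets) {
    idx <- cbind(ts$cells$row, ts$cells$col)
    levels[idx] <- levels[idx] + 1L
  }
  structure(list(spec = spec, levels = levels,
                 n_groups = length(top_sets)),
            class = "congruence_grid")
}

#' Area summary of a congruence map
#'
#' Tabulates, per congruence level >= 1, the number of cells, their area
#' (cell count times nominal cell area), the percentage of the total
#' selected area (exact in `percent`, integer-rounded in `percent_int`),
#' and cumulative ">= level" figures.
#'
#' @param cg A [congruence_map()] result.
#' @param cell_area_km2 Nominal area of one cell (e.g. 100 for 10 km
#'   cells).
#' @return data.frame: `level`, `n_cells`, `area_km2`, `percent`,
#'   `percent_int`, `cum_n_cells`, `cum_area_km2`, `cum_percent`,
#'   `cum_percent_int`; attribute `total_area_km2`.
#' @export
congruence_area_summary <- function(cg, cell_area_km2) {
  stopifnot(inherits(cg, "congruence_grid"), cell_area_km2 > 0)
  lv <- cg$levels[cg$levels > 0L]
  if (length(lv) == 0L) stop("empty congruence map: no selected cells")
  levels <- seq_len(max(lv))
  n_cells <- vapply(levels, function(l) sum(lv == l), integer(1))
  area <- n_cells * cell_area_km2
  total <- sum(area)
  cum_n <- rev(cumsum(rev(n_cells)))
  cum_area <- cum_n * cell_area_km2
  out <- data.frame(
    level = levels,
    n_cells = n_cells,
    area_km2 = area,
    percent = 100 * area / total,
    percent_int = as.integer(round(100 * area / total)),
    cum_n_cells = cum_n,
    cum_area_km2 = cum_area,
    cum_percent = 100 * cum_area / total,
    cum_percent_int = as.integer(round(100 * cum_area / total)))
  attr(out, "total_area_km2") <- total
  out
}
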