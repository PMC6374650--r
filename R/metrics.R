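# Per-species spatial rarity indices.
#
# D_max  — largest distance (km) between any pair of occurrence points;
#          a proxy for geographic range size.
# D_min  — mean over points of the distance to the nearest other point;
#          small values mean locally dense occurrences.
# local abundance — D_max / D_min; >= 1 once exact coordinate duplicates
#          are collapsed (every nearest-neighbour distance <= D_max).
# habitat specificity — number of distinct landcover classes containing
#          the points; a proxy for niche breadth.
# hull area — area (km^2) of the convex hull, the extent-of-occurrence
#          alternative used for the range-size sensitivity check.

unique_points <- function(points) {
  xy <- as.matrix(points)[, 1:2, drop = FALSE]
  unique(xy)
}

#' Maximum pairwise distance (D_max)
#'
#' The largest distance in kilometres between any pair of distinct
#' occurrence points.
#'
#' @param points Two-column matrix or data.frame of coordinates.
#' @param coord_mode `"lonlat"` or `"planar_km"`.
#' @return D_max in km.
#' @export
compute_dmax <- function(points, coord_mode = c("lonlat", "planar_km")) {
  coord_mode <- check_coord_mode(coord_mode)
  xy <- unique_points(points)
  if (nrow(xy) < 2L)
    stop("degenerate species: fewer than 2 unique points")
  max(dist_matrix_km(xy, coord_mode))
}

#' Mean nearest-neighbour distance (D_min)
#'
#' For each distinct occurrence point, the distance to its nearest other
#' point; returns the arithmetic mean over points, in kilometres.
#'
#' @inheritParams compute_dmax
#' @return D_min in km.
#' @export
compute_dmin <- function(points, coord_mode = c("lonlat", "planar_km")) {
  coord_mode <- check_coord_mode(coord_mode)
  xy <- unique_points(points)
  if (nrow(xy) < 2L)
    stop("degenerate species: fewer than 2 unique points")
  m <- dist_matrix_km(xy, coord_mode)
  diag(m) <- Inf
  mean(apply(m, 1L, min))
}

#' Local abundance ratio D_max / D_min
#'
#' Increases with range extent and with local point density. Equals 1 for
#' a two-point species; always >= 1 after duplicate collapsing.
#'
#' @param d_max_km,d_min_km Distances in km, from [compute_dmax()] /
#'   [compute_dmin()].
#' @return Dimensionless ratio >= 1.
#' @export
local_abundance_ratio <- function(d_max_km, d_min_km) {
  stopifnot(d_max_km >= 0, d_min_km >= 0)
  if (d_min_km == 0)
    stop("D_min = 0: coincident points must be collapsed before metrics")
  d_max_km / d_min_km
}

#' Habitat specificity: landcover classes occupied
#'
#' Counts the distinct non-nodata landcover classes of the cells that
#' contain the points. Points falling off-grid or on nodata cells are
#' excluded with a warning reporting how many.
#'
#' @param points Two-column matrix or data.frame of coordinates (same
#'   units as the grid).
#' @param landcover A [landcover_grid()].
#' @return Integer count >= 1.
#' @export
habitat_specificity <- function(points, landcover) {
  stopifnot(inherits(landcover, "landcover_grid"))
  xy <- as.matrix(points)[, 1:2, drop = FALSE]
  cls <- landcover_class_at(landcover, xy[, 1], xy[, 2])
  n_bad <- sum(is.na(cls))
  if (n_bad == nrow(xy))
    stop("no habitat information: all points off-grid or on nodata")
  if (n_bad > 0L)
    warning(n_bad, " point(s) off-grid or on nodata excluded from ",
            "habitat specificity")
  length(unique(cls[!is.na(cls)]))
}

#' Convex hull (extent of occurrence) area
#'
#' Area in square kilometres of the convex hull around the distinct
#' points. In `planar_km` mode this is the shoelace area of the hull; in
#' `lonlat` mode points are first projected with a Lambert azimuthal
#' equal-area projection centred at the point centroid. Fewer than 3
#' unique points, or collinear points, give `NA` and 0 respectively.
#'
#' @inheritParams compute_dmax
#' @return Area in km^2, or `NA_real_` if fewer than 3 unique points.
#' @export
convex_hull_area <- function(points, coord_mode = c("lonlat", "planar_km")) {
  coord_mode <- check_coord_mode(coord_mode)
  xy <- unique_points(points)
  if (nrow(xy) < 3L) return(NA_real_)
  if (coord_mode == "lonlat")
    xy <- project_azimuthal_equal_area(xy[, 1], xy[, 2],
                                       mean(xy[, 1]), mean(xy[, 2]))
  h <- grDevices::chull(xy[, 1], xy[, 2])
  if (length(h) < 3L) return(0)
  shoelace_area(xy[h, 1], xy[h, 2])
}

# Polygon area from ordered vertices (shoelace formula).
shoelace_area <- function(x, y) {
  j <- c(seq_along(x)[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Compute all rarity metrics per species
#'
#' Iterates the per-species indices over an occurrence dataset. Exact
#' coordinate duplicates are collapsed before any distance or hull
#' computation; species whose records collapse to a single unique point
#' are excluded with a warning (their D_min would be 0). Results are
#' independent of record order.
#'
#' @param ds An `occ_dataset` already filtered to >= 2 records/species
#'   (see [filter_species_min_records()]).
#' @param landcover Optional [landcover_grid()]; if `NULL`,
#'   `habitat_count` is `NA` and classification is impossible.
#' @return data.frame with one row per species: `species_id`, `n_obs`,
#'   `n_unique_points`, `d_max_km`, `d_min_km`, `abundance`,
#'   `habitat_count`, `hull_area_km2` (NA when `n_unique_points < 3`).
#' @export
compute_all_metrics <- function(ds, landcover = NULL) {
  stopifnot(inherits(ds, "occ_dataset"))
  if (!is.null(landcover)) stopifnot(inherits(landcover, "landcover_grid"))
  sp <- sort(unique(ds$records$species_id))
  rows <- vector("list", length(sp))
  excluded <- character(0)
  for (i in seq_along(sp)) {
    rec <- ds$records[ds$records$species_id == sp[i], , drop = FALSE]
    xy <- unique_points(rec[, c("x", "y")])
    if (nrow(xy) < 2L) {
      excluded <- c(excluded, sp[i])
      next
    }
    m <- dist_matrix_km(xy, ds$coord_mode)
    d_max <- max(m)
    diag(m) <- Inf
    d_min <- mean(apply(m, 1L, min))
    rows[[i]] <- data.frame(
      species_id = sp[i],
      n_obs = nrow(rec),
      n_unique_points = nrow(xy),
      d_max_km = d_max,
      d_min_km = d_min,
      abundance = local_abundance_ratio(d_max, d_min),
      habitat_count = if (is.null(landcover)) NA_integer_ else
        habitat_specificity(xy, landcover),
      hull_area_km2 = convex_hull_area(xy, ds$coord_mode),
      stringsAsFactors = FALSE)
  }
  if (length(excluded) > 0L)
    warning(length(excluded), " species excluded (single unique point ",
            "after duplicate collapsing): ",
            paste(utils::head(excluded, 5L), collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L)
    stop("no species with >= 2 unique points")
  rownames(out) <- NULL
  attr(out, "excluded_species") <- excluded
  out
}
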