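# Point-to-point distances. Two coordinate modes are supported and must be
# declared, never inferred: "lonlat" (degrees, great-circle) and "planar_km"
# (kilometres east/north, Euclidean).

# Mean Earth radius (IUGG), km. Used for all great-circle distances.
EARTH_RADIUS_KM <- 6371.0088

COORD_MODES <- c("lonlat", "planar_km")

check_coord_mode <- function(coord_mode) {
  match.arg(coord_mode, COORD_MODES)
}

#' Distance between two points
#'
#' Great-circle (haversine, Earth radius 6371.0088 km) distance for
#' `coord_mode = "lonlat"`, Euclidean distance for `"planar_km"`.
#' Both return kilometres.
#'
#' @param p,q Numeric vectors `c(x, y)`: lon/lat degrees or km east/north.
#' @param coord_mode `"lonlat"` or `"planar_km"`.
#' @return Distance in km.
#' @examples
#' pairwise_distance(c(0, 0), c(3, 4), "planar_km")   # 5
#' pairwise_distance(c(0, 0), c(1, 0), "lonlat")      # ~111.195
#' @export
pairwise_distance <- function(p, q, coord_mode = c("lonlat", "planar_km")) {
  coord_mode <- check_coord_mode(coord_mode)
  stopifnot(length(p) == 2L, length(q) == 2L,
            all(is.finite(p)), all(is.finite(q)))
  if (coord_mode == "planar_km") {
    sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2)
  } else {
    haversine_km(p[1], p[2], q[1], q[2])
  }
}

# Vectorized haversine; arguments in degrees.
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r
  dlon <- (lon2 - lon1) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# Full symmetric pairwise distance matrix (km) for an n x 2 coordinate
# matrix. n per species is small, so O(n^2) storage is fine.
dist_matrix_km <- function(xy, coord_mode) {
  coord_mode <- check_coord_mode(coord_mode)
  xy <- as.matrix(xy)
  if (coord_mode == "planar_km") {
    as.matrix(stats::dist(xy))
  } else {
    n <- nrow(xy)
    lon <- xy[, 1]; lat <- xy[, 2]
    m <- haversine_km(rep(lon, times = n), rep(lat, times = n),
                      rep(lon, each = n), rep(lat, each = n))
    matrix(m, n, n)
  }
}

# Lambert azimuthal equal-area projection of lon/lat degrees onto a plane
# (km) centred at (lon0, lat0). Area-true, which is what hull areas need.
project_azimuthal_equal_area <- function(lon, lat, lon0, lat0) {
  r <- pi / 180
  lam <- lon * r; phi <- lat * r
  lam0 <- lon0 * r; phi0 <- lat0 * r
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  k <- sqrt(2 / denom)
  cbind(x = EARTH_RADIUS_KM * k * cos(phi) * sin(lam - lam0),
        y = EARTH_RADIUS_KM * k *
          (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0)))
}
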