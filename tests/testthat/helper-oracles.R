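# Independent brute-force oracles. These deliberately re-derive every
# quantity with the most literal algorithm available (double loops,
# explicit interval tests, a different hull algorithm and a different
# great-circle formula) so they share no code path with the package.

oracle_euclid <- function(p, q) sqrt(sum((p - q)^2))

# Spherical law of cosines — a different great-circle formula than the
# package's haversine; adequate for well-separated points.
oracle_gc_km <- function(p, q) {
  r <- pi / 180
  s <- sin(p[2] * r) * sin(q[2] * r) +
    cos(p[2] * r) * cos(q[2] * r) * cos((q[1] - p[1]) * r)
  6371.0088 * acos(pmin(1, pmax(-1, s)))
}

oracle_dist <- function(p, q, mode) {
  if (mode == "planar_km") oracle_euclid(p, q) else oracle_gc_km(p, q)
}

oracle_dmax <- function(xy, mode = "planar_km") {
  xy <- unique(xy)
  best <- 0
  for (i in seq_len(nrow(xy) - 1)) {
    for (j in (i + 1):nrow(xy)) {
      d <- oracle_dist(as.numeric(xy[i, ]), as.numeric(xy[j, ]), mode)
      if (d > best) best <- d
    }
  }
  best
}

oracle_dmin <- function(xy, mode = "planar_km") {
  xy <- unique(xy)
  nn <- numeric(nrow(xy))
  for (i in seq_len(nrow(xy))) {
    best <- Inf
    for (j in seq_len(nrow(xy))) {
      if (i == j) next
      d <- oracle_dist(as.numeric(xy[i, ]), as.numeric(xy[j, ]), mode)
      if (d < best) best <- d
    }
    nn[i] <- best
  }
  mean(nn)
}

# Andrew's monotone chain convex hull + triangle-fan signed area:
# a different algorithm than chull + shoelace.
oracle_hull_area <- function(xy) {
  xy <- unname(unique(as.matrix(xy)))
  if (nrow(xy) < 3) return(NA_real_)
  o <- order(xy[, 1], xy[, 2])
  xy <- xy[o, , drop = FALSE]
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(pts) {
    h <- list()
    for (i in seq_len(nrow(pts))) {
      while (length(h) >= 2 &&
             cross(h[[length(h) - 1]], h[[length(h)]], pts[i, ]) <= 0)
        h[[length(h)]] <- NULL
      h[[length(h) + 1]] <- pts[i, ]
    }
    h
  }
  lower <- build(xy)
  upper <- build(xy[nrow(xy):1, , drop = FALSE])
  hull <- do.call(rbind, c(lower[-length(lower)], upper[-length(upper)]))
  if (nrow(hull) < 3) return(0)
  a <- 0
  for (i in 2:(nrow(hull) - 1))
    a <- a + cross(hull[1, ], hull[i, ], hull[i + 1, ])
  abs(a) / 2
}

# Distinct-species counting by explicit interval membership tests.
oracle_richness <- function(rec, spec) {
  m <- matrix(0L, spec$n_rows, spec$n_cols)
  for (r in seq_len(spec$n_rows)) {
    for (cc in seq_len(spec$n_cols)) {
      xlo <- spec$x0 + (cc - 1) * spec$cell_size
      ylo <- spec$y0 + (r - 1) * spec$cell_size
      inside <- rec$x >= xlo & rec$x < xlo + spec$cell_size &
        rec$y >= ylo & rec$y < ylo + spec$cell_size
      m[r, cc] <- length(unique(rec$species_id[inside]))
    }
  }
  m
}

# Tie-inclusive top-k selection via strict-rank counting.
oracle_top_cells <- function(counts, q) {
  occ <- which(counts > 0, arr.ind = TRUE)
  vals <- counts[occ]
  k <- ceiling(q * length(vals))
  keep <- vapply(vals, function(v) sum(vals > v) < k, logical(1))
  occ[keep, , drop = FALSE]
}

oracle_congruence <- function(top_sets, n_rows, n_cols) {
  m <- matrix(0L, n_rows, n_cols)
  for (r in seq_len(n_rows)) {
    for (cc in seq_len(n_cols)) {
      for (ts in top_sets) {
        if (any(ts$cells$row == r & ts$cells$col == cc))
          m[r, cc] <- m[r, cc] + 1L
      }
    }
  }
  m
}

random_points <- function(n, scale = 100) {
  data.frame(x = runif(n, 0, scale), y = runif(n, 0, scale))
}
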