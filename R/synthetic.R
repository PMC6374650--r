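# Synthetic landscapes and occurrence point patterns with known rarity
# archetypes, so the whole pipeline can be exercised and its label
# recovery measured without any field data.
#
# Mechanisms, one per rarity axis:
#   range       — points live within range_radius_km of a uniformly drawn
#                 centre (small radius <-> Narrow);
#   abundance   — Thomas-process-style clustering: offspring scattered
#                 around parent points with sd cluster_sd_km; tight
#                 clusters compress nearest-neighbour distances and so
#                 inflate D_max/D_min (<-> Large);
#   specificity — rejection sampling against an allowed subset of
#                 landcover classes (small subset <-> Restricted).
#
# All generators are pure functions of (parameters, seed).

#' Default synthetic archetype parameters
#'
#' One row per rarity class. Values were fixed once, after a single
#' calibration run, so that on a 500 km domain the realized indices span
#' ranges of the same order as a national flora analysis (D_max up to a
#' few hundred km, abundance ratios ~1-300, specificity 1-10) and the
#' eight archetypes are recoverable by the mean-cutoff classifier.
#'
#' @param n_habitat_total Number of landcover classes in the landscape
#'   the archetypes will be placed on (broad archetypes may use all of
#'   them).
#' @return data.frame with columns `label`, `range_radius_km`,
#'   `n_points_min`, `n_points_max`, `n_clusters`, `cluster_sd_km`,
#'   `n_habitat_classes`.
#' @export
archetype_defaults <- function(n_habitat_total = 10L) {
  radius <- c(N = 20, W = 170)
  out <- do.call(rbind, lapply(RARITY_CODES, function(code) {
    p <- strsplit(code, "/", fixed = TRUE)[[1]]
    r <- radius[[p[1]]]
    tight <- p[3] == "L"  # Large abundance <-> tight clusters
    data.frame(
      label = code,
      range_radius_km = r,
      n_points_min = 30L, n_points_max = 50L,
      n_clusters = if (tight) 8L else 12L,
      cluster_sd_km = if (tight) 1.0 else 0.35 * r,
      n_habitat_classes = if (p[2] == "R") 2L else as.integer(n_habitat_total),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic categorical landcover grid
#'
#' Nearest-seed (Voronoi) patches: `ceiling(area / patch_scale_km^2)`
#' patch seeds are scattered uniformly and each grid cell takes the class
#' of its nearest seed. Classes are assigned to patches round-robin, so
#' all `n_classes` codes are present whenever there are at least
#' `n_classes` patches and enough cells.
#'
#' @param spec A [build_grid()] result (planar km units).
#' @param n_classes Number of landcover classes K >= 1.
#' @param patch_scale_km Typical patch diameter; smaller values give a
#'   finer habitat mosaic.
#' @param seed Required integer seed; the same seed gives a bit-identical
#'   raster.
#' @return A [landcover_grid()].
#' @export
generate_landcover <- function(spec, n_classes, patch_scale_km, seed) {
  stopifnot(inherits(spec, "grid_spec"), n_classes >= 1L,
            patch_scale_km > 0)
  w <- spec$n_cols * spec$cell_size
  h <- spec$n_rows * spec$cell_size
  n_patches <- max(n_classes, ceiling(w * h / patch_scale_km^2))
  with_seed(seed, {
    sx <- runif(n_patches, spec$x0, spec$x0 + w)
    sy <- runif(n_patches, spec$y0, spec$y0 + h)
    patch_class <- rep_len(seq_len(n_classes), n_patches)[
      sample.int(n_patches)]
    cx <- spec$x0 + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
    cy <- spec$y0 + (seq_len(spec$n_rows) - 0.5) * spec$cell_size
    classes <- matrix(0L, spec$n_rows, spec$n_cols)
    # chunk rows so the cell-by-seed distance matrix stays small
    block <- max(1L, floor(4e6 / n_patches))
    for (start in seq(1L, spec$n_rows, by = block)) {
      rows <- start:min(start + block - 1L, spec$n_rows)
      gx <- rep(cx, times = length(rows))
      gy <- rep(cy[rows], each = spec$n_cols)
      d2 <- outer(gx, sx, "-")^2 + outer(gy, sy, "-")^2
      nearest <- max.col(-d2, ties.method = "first")
      classes[rows, ] <- matrix(patch_class[nearest],
                                nrow = length(rows),
                                ncol = spec$n_cols, byrow = TRUE)
    }
    landcover_grid(classes, spec$x0, spec$y0, spec$cell_size)
  })
}

#' Generate occurrence points for one synthetic species
#'
#' Draws a range centre uniformly over the extent, places `n_clusters`
#' parent points uniformly in the disc of `range_radius_km` around it —
#' resampled until each parent is inside the extent *and on one of the
#' species' allowed landcover classes* (a habitat specialist's local
#' populations sit in its habitat); if the disc holds no allowed habitat
#' the centre itself is redrawn. Offspring are then scattered around
#' uniformly chosen parents with isotropic Gaussian offsets of sd
#' `cluster_sd_km`, truncated at 4 sd. Offspring falling off-grid, on
#' nodata, or on a disallowed landcover class are rejected and redrawn
#' (capped at 1000 tries per requested point), which ties realized
#' habitat counts to `n_habitat_classes`. The truncation makes
#' `D_max <= 2 * (range_radius_km + 4 * cluster_sd_km)` a deterministic
#' guarantee.
#'
#' @param arch One row of [archetype_defaults()] (data.frame or list).
#' @param landcover A [landcover_grid()].
#' @param extent `c(xmin, xmax, ymin, ymax)` for the range centre.
#' @param seed Required integer seed.
#' @return data.frame of records: `species_id` (empty, filled by the
#'   dataset generator), `x`, `y`; attribute `allowed_classes`.
#' @export
generate_species_occurrences <- function(arch, landcover, extent, seed) {
  stopifnot(inherits(landcover, "landcover_grid"), length(extent) == 4L)
  arch <- as.list(arch)
  stopifnot(arch$range_radius_km > 0,
            arch$cluster_sd_km < arch$range_radius_km,
            arch$n_habitat_classes >= 1L,
            arch$n_habitat_classes <= landcover$n_classes)
  with_seed(seed, {
    n <- if (arch$n_points_max > arch$n_points_min)
      sample(arch$n_points_min:arch$n_points_max, 1L) else arch$n_points_min
    allowed <- sort(sample(landcover$class_codes, arch$n_habitat_classes))
    # centre + parents: parents uniform in the range disc, accepted only
    # inside the extent and on allowed habitat; redraw the centre if the
    # disc holds no reachable habitat
    px <- py <- NULL
    for (attempt in 1:50) {
      center <- c(runif(1, extent[1], extent[2]),
                  runif(1, extent[3], extent[4]))
      r <- arch$range_radius_km * sqrt(runif(1000 * arch$n_clusters))
      th <- runif(1000 * arch$n_clusters, 0, 2 * pi)
      cx <- center[1] + r * cos(th)
      cy <- center[2] + r * sin(th)
      ok <- cx >= extent[1] & cx <= extent[2] &
        cy >= extent[3] & cy <= extent[4] &
        landcover_class_at(landcover, cx, cy) %in% allowed
      if (sum(ok, na.rm = TRUE) >= arch$n_clusters) {
        idx <- which(ok)[seq_len(arch$n_clusters)]
        px <- cx[idx]; py <- cy[idx]
        break
      }
    }
    if (is.null(px))
      stop("could not place cluster parents on allowed habitat for ",
           "archetype ", arch$label)
    xs <- ys <- numeric(0)
    tries <- 0L
    max_tries <- 1000L * n
    while (length(xs) < n && tries < max_tries) {
      m <- n - length(xs)
      pid <- sample.int(arch$n_clusters, m, replace = TRUE)
      dx <- rnorm(m, 0, arch$cluster_sd_km)
      dy <- rnorm(m, 0, arch$cluster_sd_km)
      # truncate offsets at 4 sd (resample the tail)
      bad <- which(dx^2 + dy^2 > (4 * arch$cluster_sd_km)^2)
      while (length(bad) > 0L) {
        dx[bad] <- rnorm(length(bad), 0, arch$cluster_sd_km)
        dy[bad] <- rnorm(length(bad), 0, arch$cluster_sd_km)
        bad <- bad[dx[bad]^2 + dy[bad]^2 > (4 * arch$cluster_sd_km)^2]
      }
      cx <- px[pid] + dx
      cy <- py[pid] + dy
      cls <- landcover_class_at(landcover, cx, cy)
      ok <- !is.na(cls) & cls %in% allowed
      xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
      tries <- tries + m
    }
    if (length(xs) < 2L)
      stop("could not place >= 2 points for archetype ", arch$label,
           " after ", max_tries, " tries")
    out <- data.frame(species_id = "", x = xs[seq_len(min(n, length(xs)))],
                      y = ys[seq_len(min(n, length(ys)))],
                      stringsAsFactors = FALSE)
    attr(out, "allowed_classes") <- allowed
    out
  })
}

#' Generate a full synthetic archetype dataset
#'
#' Produces a landcover landscape, a set of species per archetype with
#' deterministic names (`NRS_0001`, ...), and the ground-truth table used
#' by [recovery_report()]. Coordinates are planar km.
#'
#' @param n_per_class Species per archetype (default 10).
#' @param seed Required integer seed; all child seeds derive from it.
#' @param extent_km Side length of the square domain (default 500).
#' @param n_classes Number of landcover classes (default 10).
#' @param patch_scale_km Landcover patch scale (default 12).
#' @param cell_size_km Landcover cell size (default 4).
#' @param archetypes Parameter table, default [archetype_defaults()].
#' @return List: `dataset` (an `occ_dataset`), `landcover`
#'   (a `landcover_grid`), `truth` (data.frame `species_id`, `label`),
#'   `extent`.
#' @export
generate_archetype_dataset <- function(n_per_class = 10L, seed,
                                       extent_km = 500,
                                       n_classes = 10L,
                                       patch_scale_km = 12,
                                       cell_size_km = 4,
                                       archetypes = NULL) {
  if (is.null(archetypes)) archetypes <- archetype_defaults(n_classes)
  extent <- c(0, extent_km, 0, extent_km)
  spec <- build_grid(extent, cell_size_km)
  landcover <- generate_landcover(spec, n_classes, patch_scale_km,
                                  seed = seed)
  recs <- list()
  truth <- list()
  counter <- 0L
  for (a in seq_len(nrow(archetypes))) {
    arch <- archetypes[a, , drop = FALSE]
    tag <- gsub("/", "", arch$label, fixed = TRUE)
    for (i in seq_len(n_per_class)) {
      counter <- counter + 1L
      sp_id <- sprintf("%s_%04d", tag, i)
      r <- generate_species_occurrences(
        arch, landcover, extent, seed = derive_seed(seed, counter))
      r$species_id <- sp_id
      recs[[counter]] <- r
      truth[[counter]] <- data.frame(species_id = sp_id,
                                     label = arch$label,
                                     stringsAsFactors = FALSE)
    }
  }
  list(dataset = occurrence_dataset(do.call(rbind, recs),
                                    coord_mode = "planar_km",
                                    source = sprintf("synthetic seed=%d",
                                                     as.integer(seed))),
       landcover = landcover,
       truth = do.call(rbind, truth),
       extent = extent)
}

#' Archetype recovery report
#'
#' Compares the pipeline's class assignments with the generator's ground
#' truth: an 8x8 confusion matrix, overall accuracy (trace / total), and
#' the per-axis binary accuracies for range, specificity and abundance.
#'
#' @param truth data.frame `species_id`, `label` from
#'   [generate_archetype_dataset()].
#' @param result A [classify_species()] result on the same species.
#' @return Object of class `recovery_report`: `confusion` (truth rows x
#'   predicted columns), `accuracy`, `axis_accuracy` (named: range,
#'   specificity, abundance), `n`.
#' @export
recovery_report <- function(truth, result) {
  stopifnot(is.data.frame(truth),
            inherits(result, "rarity_classification"))
  asn <- result$assignments
  only_truth <- setdiff(truth$species_id, asn$species_id)
  only_pred <- setdiff(asn$species_id, truth$species_id)
  if (length(only_truth) > 0L || length(only_pred) > 0L)
    stop("species mismatch between truth and classification; ",
         "only in truth: ", paste(utils::head(only_truth, 5), collapse = ", "),
         "; only in prediction: ",
         paste(utils::head(only_pred, 5), collapse = ", "))
  m <- merge(truth, asn[, c("species_id", "code")], by = "species_id")
  confusion <- table(
    truth = factor(m$label, levels = RARITY_CODES),
    predicted = factor(m$code, levels = RARITY_CODES))
  letters_of <- function(codes, k)
    vapply(strsplit(codes, "/", fixed = TRUE), `[[`, "", k)
  axis_acc <- vapply(1:3, function(k)
    mean(letters_of(m$label, k) == letters_of(m$code, k)), numeric(1))
  structure(list(
    confusion = confusion,
    accuracy = sum(diag(confusion)) / nrow(m),
    axis_accuracy = stats::setNames(axis_acc,
                                    c("range", "specificity", "abundance")),
    n = nrow(m)),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> n=", x$n,
      " overall accuracy=", round(x$accuracy, 3),
      "\n  per-axis: range=", round(x$axis_accuracy["range"], 3),
      " specificity=", round(x$axis_accuracy["specificity"], 3),
      " abundance=", round(x$axis_accuracy["abundance"], 3), "\n",
      sep = "")
  invisible(x)
}
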