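# Eight-class rarity assignment.
#
# Each of the three indices is binarized at an arithmetic-mean cutoff.
# Range uses the mean D_max over all species. Abundance and specificity
# cutoffs are, by default, computed within the narrow and wide range
# groups separately ("within_group"); a single global mean is available
# via mode = "global". Values exactly at a cutoff go to the non-rare side
# (Wide / Broad / Large).

#' Compute mean-based classification cutoffs
#'
#' @param metrics Metrics table from [compute_all_metrics()];
#'   `habitat_count` must be populated.
#' @param mode `"within_group"` (default): abundance and specificity means
#'   are taken separately inside the narrow and wide range groups.
#'   `"global"`: one mean over all species per index.
#' @return An object of class `cutoff_set`: list with `range_cutoff_km`,
#'   `abundance_cutoff` and `specificity_cutoff` (each a named vector
#'   `c(narrow=, wide=)`), and `mode`.
#' @export
compute_cutoffs <- function(metrics, mode = c("within_group", "global")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 2L)
  if (any(is.na(metrics$habitat_count)))
    stop("habitat_count has NA values; supply a landcover grid when ",
         "computing metrics")
  range_cutoff <- mean(metrics$d_max_km)
  narrow <- metrics$d_max_km < range_cutoff
  if (mode == "within_group") {
    if (!any(narrow) || all(narrow))
      stop("empty narrow or wide range group; use mode = \"global\"")
    ab <- c(narrow = mean(metrics$abundance[narrow]),
            wide = mean(metrics$abundance[!narrow]))
    sp <- c(narrow = mean(metrics$habitat_count[narrow]),
            wide = mean(metrics$habitat_count[!narrow]))
  } else {
    ab <- rep(mean(metrics$abundance), 2L)
    sp <- rep(mean(metrics$habitat_count), 2L)
    names(ab) <- names(sp) <- c("narrow", "wide")
  }
  structure(list(range_cutoff_km = range_cutoff,
                 abundance_cutoff = ab,
                 specificity_cutoff = sp,
                 mode = mode),
            class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat("<cutoff_set> mode=", x$mode,
      "\n  range:       D_max <", format(x$range_cutoff_km),
      "km -> Narrow\n  specificity: habitat <",
      format(x$specificity_cutoff["narrow"]), "(narrow) /",
      format(x$specificity_cutoff["wide"]), "(wide) -> Restricted",
      "\n  abundance:   ratio <",
      format(x$abundance_cutoff["narrow"]), "(narrow) /",
      format(x$abundance_cutoff["wide"]), "(wide) -> Small\n")
  invisible(x)
}

#' Assign the rarity class of one species
#'
#' Pure function of the index values and the cutoffs: Narrow iff
#' `d_max_km < range_cutoff_km`; then, within the resulting range group,
#' Restricted iff `habitat_count < specificity_cutoff[group]` and Small
#' iff `abundance < abundance_cutoff[group]`. Ties go to Wide/Broad/Large.
#'
#' @param d_max_km,abundance,habitat_count Index values (vectorized).
#' @param cutoffs A [compute_cutoffs()] result.
#' @return Character vector of class codes (see [rarity_codes()]).
#' @export
assign_rarity_class <- function(d_max_km, abundance, habitat_count,
                                cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_set"),
            all(habitat_count >= 1, na.rm = FALSE))
  narrow <- d_max_km < cutoffs$range_cutoff_km
  group <- ifelse(narrow, "narrow", "wide")
  restricted <- habitat_count < cutoffs$specificity_cutoff[group]
  small <- abundance < cutoffs$abundance_cutoff[group]
  paste(ifelse(narrow, "N", "W"),
        ifelse(restricted, "R", "B"),
        ifelse(small, "S", "L"), sep = "/")
}

#' Classify every species and summarize class counts
#'
#' @param metrics Metrics table from [compute_all_metrics()].
#' @param cutoffs A [compute_cutoffs()] result (computed from `metrics`
#'   if omitted).
#' @return An object of class `rarity_classification`: list with
#'   `assignments` (data.frame: species_id, code, range/specificity/
#'   abundance binary labels, the three index values), `class_counts`
#'   (named integer over the 8 codes), `class_percent` (same order, one
#'   decimal), `n_classified`, and `cutoffs`.
#' @export
classify_species <- function(metrics, cutoffs = NULL) {
  if (is.null(cutoffs)) cutoffs <- compute_cutoffs(metrics)
  code <- assign_rarity_class(metrics$d_max_km, metrics$abundance,
                              metrics$habitat_count, cutoffs)
  parts <- do.call(rbind, strsplit(code, "/", fixed = TRUE))
  assignments <- data.frame(
    species_id = metrics$species_id,
    code = code,
    range = ifelse(parts[, 1] == "N", "Narrow", "Wide"),
    specificity = ifelse(parts[, 2] == "R", "Restricted", "Broad"),
    abundance_class = ifelse(parts[, 3] == "S", "Small", "Large"),
    d_max_km = metrics$d_max_km,
    abundance = metrics$abundance,
    habitat_count = metrics$habitat_count,
    stringsAsFactors = FALSE)
  counts <- table(factor(code, levels = RARITY_CODES))
  counts <- stats::setNames(as.integer(counts), RARITY_CODES)
  structure(list(
    assignments = assignments,
    class_counts = counts,
    class_percent = round(100 * counts / sum(counts), 1L),
    n_classified = length(code),
    cutoffs = cutoffs),
    class = "rarity_classification")
}

#' @export
print.rarity_classification <- function(x, ...) {
  cat("<rarity_classification> ", x$n_classified, " species\n", sep = "")
  print(data.frame(code = RARITY_CODES,
                   count = unname(x$class_counts),
                   percent = unname(x$class_percent)))
  invisible(x)
}

#' Cross-tabulate rarity classes against species lists
#'
#' For each class and each list, counts the classified species whose id
#' appears in the list (the Table-1-style columns such as endangered /
#' endemic / IUCN). List members absent from the classification are
#' reported in the `"missing"` attribute.
#'
#' @param result A [classify_species()] result.
#' @param ... Named `species_list` objects (see [read_species_list()]) or
#'   character vectors of species ids.
#' @return data.frame: one row per class code (plus a `Total` row), one
#'   column per list; attribute `missing` names list members that were
#'   not classified.
#' @export
crosstab_with_lists <- function(result, ...) {
  stopifnot(inherits(result, "rarity_classification"))
  lists <- list(...)
  if (length(lists) == 0L) stop("no species lists supplied")
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    stop("species lists must be named")
  lists <- lapply(lists, function(l)
    if (inherits(l, "species_list")) l$names else as.character(l))
  asn <- result$assignments
  cols <- lapply(lists, function(members)
    vapply(RARITY_CODES, function(cd)
      sum(asn$code == cd & asn$species_id %in% members), integer(1)))
  out <- data.frame(code = RARITY_CODES, cols,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(code = "Total",
                               lapply(cols, sum), check.names = FALSE))
  attr(out, "missing") <- lapply(lists, function(members)
    sort(setdiff(members, asn$species_id)))
  out
}

#' Agreement between D_max and convex-hull range classification
#'
#' Sensitivity check for the choice of range-size metric: species with a
#' defined hull area (>= 3 unique points) are classified narrow/wide
#' twice — once by D_max against the mean D_max, once by hull area
#' against the mean hull area, both means over the same eligible species
#' — and the fraction receiving the same binary label is returned.
#'
#' @param metrics Metrics table from [compute_all_metrics()].
#' @return Agreement rate in `[0, 1]`, with attributes `n_eligible`,
#'   `dmax_cutoff_km`, `hull_cutoff_km2`.
#' @export
range_size_agreement <- function(metrics) {
  el <- metrics[!is.na(metrics$hull_area_km2), , drop = FALSE]
  if (nrow(el) == 0L)
    stop("no species with a defined hull area (need >= 3 unique points)")
  dmax_cut <- mean(el$d_max_km)
  hull_cut <- mean(el$hull_area_km2)
  narrow_d <- el$d_max_km < dmax_cut
  narrow_h <- el$hull_area_km2 < hull_cut
  structure(mean(narrow_d == narrow_h),
            n_eligible = nrow(el),
            dmax_cutoff_km = dmax_cut,
            hull_cutoff_km2 = hull_cut)
}
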