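# Occurrence-table I/O and validation.

#' Construct an occurrence dataset
#'
#' Low-level constructor. `records` must have columns `species_id`, `x`,
#' `y` and optionally `date`. The coordinate mode is a dataset-level
#' declaration and is never inferred from the data; mixing modes is
#' impossible by construction.
#'
#' @param records data.frame with columns `species_id`, `x`, `y`
#'   (and optionally `date`).
#' @param coord_mode `"lonlat"` (degrees) or `"planar_km"` (km east/north).
#' @param source Free-text provenance string.
#' @return An object of class `occ_dataset`.
#' @export
occurrence_dataset <- function(records, coord_mode = c("lonlat", "planar_km"),
                               source = "") {
  coord_mode <- check_coord_mode(coord_mode)
  stopifnot(is.data.frame(records),
            all(c("species_id", "x", "y") %in% names(records)))
  records$species_id <- as.character(records$species_id)
  if (any(!nzchar(trimws(records$species_id))))
    stop("species_id must never be empty")
  records$x <- as.numeric(records$x)
  records$y <- as.numeric(records$y)
  if (any(!is.finite(records$x)) || any(!is.finite(records$y)))
    stop("non-finite coordinates in records")
  if (coord_mode == "lonlat") {
    bad <- records$x < -180 | records$x > 180 |
      records$y < -90 | records$y > 90
    if (any(bad))
      stop("lonlat coordinates out of range in ", sum(bad), " record(s)")
  }
  if (nrow(records) == 0L) stop("occurrence dataset has no records")
  if (!"date" %in% names(records)) records$date <- NA_character_
  rownames(records) <- NULL
  structure(
    list(records = records[, c("species_id", "x", "y", "date")],
         coord_mode = coord_mode, source = source),
    class = "occ_dataset")
}

#' @export
print.occ_dataset <- function(x, ...) {
  cat("<occ_dataset> ", nrow(x$records), " records, ",
      length(unique(x$records$species_id)), " species, coord_mode=",
      x$coord_mode, "\n", sep = "")
  invisible(x)
}

#' Number of species in a dataset
#' @param ds An `occ_dataset`.
#' @return Integer count of distinct species.
#' @export
n_species <- function(ds) length(unique(ds$records$species_id))

#' Read an occurrence table from CSV
#'
#' Reads a comma-separated UTF-8 table with a header row. Rows with an
#' empty species cell or unparseable / out-of-range coordinates are dropped
#' with a warning that reports the count; they are never silently lost.
#'
#' @param path CSV file path.
#' @param coord_mode `"lonlat"` or `"planar_km"` (declared, not inferred).
#' @param col_species,col_x,col_y,col_date Column names in the file.
#'   `col_date` is optional; set `NULL` to ignore dates.
#' @return An `occ_dataset`. The number of dropped rows is available as
#'   `attr(ds, "n_dropped")`.
#' @export
read_occurrences <- function(path, coord_mode = c("lonlat", "planar_km"),
                             col_species = "species", col_x = "x",
                             col_y = "y", col_date = "date") {
  coord_mode <- check_coord_mode(coord_mode)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         encoding = "UTF-8", check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty occurrence file: ", path)
  for (col in c(col_species, col_x, col_y)) {
    if (!col %in% names(raw))
      stop("missing required column '", col, "' in ", path)
  }
  sp <- trimws(as.character(raw[[col_species]]))
  x <- suppressWarnings(as.numeric(raw[[col_x]]))
  y <- suppressWarnings(as.numeric(raw[[col_y]]))
  ok <- nzchar(sp) & !is.na(sp) & is.finite(x) & is.finite(y)
  if (coord_mode == "lonlat")
    ok <- ok & x >= -180 & x <= 180 & y >= -90 & y <= 90
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    warning("dropped ", n_dropped,
            " record(s) with missing species or invalid coordinates")
  if (!any(ok)) stop("no valid occurrence records in ", path)
  date <- if (!is.null(col_date) && col_date %in% names(raw))
    as.character(raw[[col_date]]) else NA_character_
  ds <- occurrence_dataset(
    data.frame(species_id = sp[ok], x = x[ok], y = y[ok],
               date = if (length(date) > 1L) date[ok] else date,
               stringsAsFactors = FALSE),
    coord_mode = coord_mode, source = path)
  attr(ds, "n_dropped") <- n_dropped
  ds
}

#' Keep only species with a minimum number of records
#'
#' Species observed fewer than `min_n` times carry too little spatial
#' information for distance-based range metrics; the default of 2 is the
#' minimum at which a maximum pairwise distance exists at all.
#'
#' @param ds An `occ_dataset`.
#' @param min_n Minimum records per species (default 2).
#' @return A list with elements `dataset` (the filtered `occ_dataset`) and
#'   `report` (list: `n_species_in`, `n_records_in`, `n_species_kept`,
#'   `n_records_kept`, `n_species_dropped`, `n_records_dropped`,
#'   `dropped_species`).
#' @export
filter_species_min_records <- function(ds, min_n = 2L) {
  stopifnot(inherits(ds, "occ_dataset"), min_n >= 1L)
  counts <- table(ds$records$species_id)
  keep_sp <- names(counts)[counts >= min_n]
  drop_sp <- setdiff(names(counts), keep_sp)
  if (length(keep_sp) == 0L)
    stop("all species have fewer than ", min_n, " records")
  keep <- ds$records$species_id %in% keep_sp
  report <- list(
    n_species_in = length(counts),
    n_records_in = nrow(ds$records),
    n_species_kept = length(keep_sp),
    n_records_kept = sum(keep),
    n_species_dropped = length(drop_sp),
    n_records_dropped = sum(!keep),
    dropped_species = sort(drop_sp))
  out <- ds
  out$records <- ds$records[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  list(dataset = out, report = report)
}

#' Read a species list (one name per line)
#'
#' Blank lines and lines starting with `#` are ignored; names are trimmed
#' and duplicates collapsed.
#'
#' @param path Plain-text file path.
#' @param label One of `"endangered"`, `"endemic"`, `"iucn"`, `"custom"`.
#' @return An object of class `species_list`: list with `label` and
#'   `names` (a character set).
#' @export
read_species_list <- function(path,
                              label = c("custom", "endangered",
                                        "endemic", "iucn")) {
  label <- match.arg(label)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  nm <- unique(lines)
  if (length(nm) == 0L)
    stop("species list is empty after removing comments/blanks: ", path)
  structure(list(label = label, names = nm), class = "species_list")
}

#' Write a table deterministically
#'
#' Writes CSV or TSV with a stable column order, rows sorted by the first
#' column, and floats rounded to `digits` significant digits so that
#' write-then-read round-trips within the declared precision.
#'
#' @param rows A data.frame.
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @param digits Significant digits for numeric (non-integer) columns.
#' @return Invisibly, the path.
#' @export
write_table <- function(rows, path, format = c("csv", "tsv"), digits = 4L) {
  format <- match.arg(format)
  stopifnot(is.data.frame(rows))
  if (nrow(rows) > 0L) {
    rows <- rows[order(rows[[1]]), , drop = FALSE]
    num <- vapply(rows, function(col)
      is.double(col) && !all(col == round(col), na.rm = TRUE), logical(1))
    rows[num] <- lapply(rows[num], signif, digits = digits)
  }
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
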