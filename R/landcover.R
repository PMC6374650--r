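# Categorical landcover rasters, read and written as ESRI ASCII grids.
# The class matrix is stored south-up: row 1 is the bottom (southernmost)
# row, so matrix indices line up with the grid arithmetic in grid.R.
# ESRI ASCII files are north-up, so read/write flip row order.

#' Construct a landcover grid
#'
#' @param classes Integer matrix of class codes, row 1 = southernmost row.
#' @param x0,y0 Coordinates of the lower-left corner of the grid (same
#'   units as the occurrence coordinates).
#' @param cell_size Cell edge length (km or degrees).
#' @param nodata Integer code marking cells with no class.
#' @return An object of class `landcover_grid` with fields `x0`, `y0`,
#'   `cell_size`, `n_rows`, `n_cols`, `classes`, `nodata`, `class_codes`,
#'   `n_classes`.
#' @export
landcover_grid <- function(classes, x0, y0, cell_size, nodata = -9999L) {
  stopifnot(is.matrix(classes), cell_size > 0)
  storage.mode(classes) <- "integer"
  codes <- sort(unique(classes[classes != nodata & !is.na(classes)]))
  if (length(codes) == 0L) stop("no landcover classes (grid is all nodata)")
  structure(
    list(x0 = x0, y0 = y0, cell_size = cell_size,
         n_rows = nrow(classes), n_cols = ncol(classes),
         classes = classes, nodata = as.integer(nodata),
         class_codes = codes, n_classes = length(codes)),
    class = "landcover_grid")
}

#' @export
print.landcover_grid <- function(x, ...) {
  cat("<landcover_grid> ", x$n_rows, "x", x$n_cols, " cells of ",
      x$cell_size, ", ", x$n_classes, " classes, origin (",
      x$x0, ", ", x$y0, ")\n", sep = "")
  invisible(x)
}

#' Read an ESRI ASCII landcover grid
#'
#' Supports the standard header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`); header keys are
#' case-insensitive. The number of data values must match `nrows * ncols`.
#'
#' @param path `.asc` file path.
#' @return A [landcover_grid()].
#' @export
read_landcover_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && tolower(tok[1]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
          "nodata_value")) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss) > 0L)
    stop("ASCII grid header missing: ", paste(miss, collapse = ", "))
  nodata <- as.integer(hdr[["nodata_value"]] %||% -9999)
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("ASCII grid shape mismatch: header says ", nr, "x", nc,
         " but file has ", length(vals), " values")
  # file rows run north -> south; flip to the south-up internal layout
  m <- matrix(as.integer(vals), nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]
  landcover_grid(m, x0 = hdr$xllcorner, y0 = hdr$yllcorner,
                 cell_size = hdr$cellsize, nodata = nodata)
}

#' Write an ESRI ASCII landcover grid
#'
#' Inverse of [read_landcover_grid()]: a write-then-read round trip
#' reproduces the class matrix exactly.
#'
#' @param grid A [landcover_grid()] (or an integer matrix via
#'   [richness_grid()]-style wrappers).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_landcover_grid <- function(grid, path) {
  stopifnot(inherits(grid, "landcover_grid"))
  write_ascii_grid(grid$classes, grid$x0, grid$y0, grid$cell_size,
                   grid$nodata, path)
}

# Shared ASCII writer for any south-up integer matrix.
write_ascii_grid <- function(m, x0, y0, cell_size, nodata, path) {
  hdr <- c(paste("ncols", ncol(m)),
           paste("nrows", nrow(m)),
           paste("xllcorner", format(x0, scientific = FALSE)),
           paste("yllcorner", format(y0, scientific = FALSE)),
           paste("cellsize", format(cell_size, scientific = FALSE)),
           paste("NODATA_value", nodata))
  body <- apply(m[nrow(m):1, , drop = FALSE], 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# Class code of the cell containing each point; NA for off-grid or nodata.
landcover_class_at <- function(grid, x, y) {
  col <- floor((x - grid$x0) / grid$cell_size) + 1
  row <- floor((y - grid$y0) / grid$cell_size) + 1
  out <- rep(NA_integer_, length(x))
  inside <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  idx <- which(inside)
  if (length(idx) > 0L) {
    cls <- grid$classes[cbind(row[idx], col[idx])]
    cls[cls == grid$nodata] <- NA_integer_
    out[idx] <- cls
  }
  out
}
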