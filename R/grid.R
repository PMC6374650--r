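# Regular analysis grids. Cells are half-open: cell (1,1) covers
# [x0, x0 + s) x [y0, y0 + s); a point exactly on an interior boundary
# belongs to the higher-index cell, and points on the outer upper/right
# edge are outside.

#' Build a grid specification covering an extent
#'
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)`.
#' @param cell_size Cell edge (km for planar data, degrees for lonlat).
#' @return Object of class `grid_spec`: `x0`, `y0`, `cell_size`,
#'   `n_rows`, `n_cols`. Row/col counts are `ceiling(span / cell_size)`,
#'   at least 1 even for a degenerate zero-span extent.
#' @export
build_grid <- function(extent, cell_size) {
  stopifnot(length(extent) == 4L, cell_size > 0,
            extent[2] >= extent[1], extent[4] >= extent[3])
  structure(list(
    x0 = extent[1], y0 = extent[3], cell_size = cell_size,
    n_rows = max(1L, ceiling((extent[4] - extent[3]) / cell_size)),
    n_cols = max(1L, ceiling((extent[2] - extent[1]) / cell_size))),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat("<grid_spec> ", x$n_rows, "x", x$n_cols, " cells of ", x$cell_size,
      ", origin (", x$x0, ", ", x$y0, ")\n", sep = "")
  invisible(x)
}

#' Assign points to grid cells
#'
#' Half-open binning: interior boundaries belong to the higher-index
#' cell; the outer upper/right boundary is outside.
#'
#' @param x,y Coordinate vectors.
#' @param spec A [build_grid()] result.
#' @return data.frame with integer columns `row`, `col` (1-based; `NA`
#'   for points outside the grid).
#' @export
assign_point_to_cell <- function(x, y, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  col <- floor((x - spec$x0) / spec$cell_size) + 1
  row <- floor((y - spec$y0) / spec$cell_size) + 1
  outside <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  row[outside] <- NA_integer_
  col[outside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

grid_specs_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-9))
}
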