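#' Create a raster grid specification
#'
#' A `grid_spec` fixes the georeferencing shared by every raster in an
#' analysis: the lower-left corner of the extent, the (square) cell size in
#' metres, and the grid dimensions. Internally row 1 is the **southernmost**
#' row; writers reorder rows for file formats that store north-up.
#'
#' @param origin_x,origin_y Easting/northing of the lower-left corner (m).
#' @param cellsize Cell edge length (m). Default 6.096 m, i.e. a 20-ft cell.
#' @param nrows,ncols Grid dimensions.
#' @param nodata Sentinel written to files for missing cells. In memory,
#'   missing cells are always `NA`.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(0, 0, cellsize = 1, nrows = 4, ncols = 5)
#' @export
grid_spec <- function(origin_x, origin_y, cellsize = 6.096, nrows, ncols,
                      nodata = -9999) {
  stopifnot(is.numeric(origin_x), is.numeric(origin_y), is.finite(origin_x),
            is.finite(origin_y), cellsize > 0, nrows >= 1, ncols >= 1)
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cellsize = as.numeric(cellsize), nrows = as.integer(nrows),
         ncols = as.integer(ncols), nodata = as.numeric(nodata)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.6g m, origin (%.6g, %.6g)\n",
              x$nrows, x$ncols, x$cellsize, x$origin_x, x$origin_y))
  invisible(x)
}

spec_identical <- function(a, b) {
  isTRUE(all.equal(a[c("origin_x", "origin_y", "cellsize")],
                   b[c("origin_x", "origin_y", "cellsize")],
                   tolerance = 0)) &&
    a$nrows == b$nrows && a$ncols == b$ncols
}

#' Create a raster on a grid specification
#'
#' The single raster container used throughout the package, for elevation
#' surfaces, categorical land cover, intensity counts and covariate layers
#' alike. Values are stored as an `nrows x ncols` matrix with row 1 the
#' southernmost row; missing cells are `NA`.
#'
#' @param spec A [grid_spec()].
#' @param values A matrix of dim `c(spec$nrows, spec$ncols)`, or a single
#'   value recycled to the full grid. `NA` marks nodata.
#' @return An object of class `ces_raster` with fields `spec` and `values`.
#' @export
ces_raster <- function(spec, values = NA_real_) {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1L)
    values <- matrix(values, spec$nrows, spec$ncols)
  stopifnot(is.matrix(values), nrow(values) == spec$nrows,
            ncol(values) == spec$ncols)
  storage.mode(values) <- "double"
  structure(list(spec = spec, values = values), class = "ces_raster")
}

#' @export
print.ces_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf("<ces_raster> %d x %d, %.6g m cells, %d nodata, range [%s, %s]\n",
              x$spec$nrows, x$spec$ncols, x$spec$cellsize, sum(is.na(v)),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE)))))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param spec A [grid_spec()].
#' @return A list with vectors `x` (length `ncols`) and `y` (length `nrows`)
#'   of cell-centre eastings and northings, south-to-north.
#' @export
cell_centers <- function(spec) {
  list(x = spec$origin_x + (seq_len(spec$ncols) - 0.5) * spec$cellsize,
       y = spec$origin_y + (seq_len(spec$nrows) - 0.5) * spec$cellsize)
}

#' Locate points on a grid
#'
#' Maps coordinates to 1-based (row, col) indices using half-open cell
#' intervals `[x0, x0 + cellsize)`: a point on a shared edge belongs to the
#' cell with the larger index. Points outside the extent map to `NA`.
#'
#' @param spec A [grid_spec()].
#' @param x,y Coordinate vectors (m).
#' @return A data.frame with integer columns `row` and `col`.
#' @export
point_cell <- function(spec, x, y) {
  col <- floor((x - spec$origin_x) / spec$cellsize) + 1
  row <- floor((y - spec$origin_y) / spec$cellsize) + 1
  bad <- !is.finite(x) | !is.finite(y) |
    col < 1 | col > spec$ncols | row < 1 | row > spec$nrows
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' @param path File path (`.asc`). The six-line header (`ncols`, `nrows`,
#'   `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) is required.
#' @return A [ces_raster()]; file nodata cells become `NA`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  stopifnot(!is.null(hdr$ncols), !is.null(hdr$nrows))
  spec <- grid_spec(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                    hdr$nrows, hdr$ncols,
                    nodata = if (is.null(hdr$nodata_value)) -9999
                             else hdr$nodata_value)
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  stopifnot(length(vals) == spec$nrows * spec$ncols)
  m <- matrix(vals, nrow = spec$nrows, ncol = spec$ncols, byrow = TRUE)
  m[m == spec$nodata] <- NA_real_
  m <- m[spec$nrows:1, , drop = FALSE]  # file is north-up; row 1 = south
  ces_raster(spec, m)
}

#' Write an ESRI ASCII grid
#'
#' Values are written with 17 significant digits so that a read/write
#' round-trip reproduces doubles bit-exactly.
#'
#' @param r A [ces_raster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path) {
  stopifnot(inherits(r, "ces_raster"))
  s <- r$spec
  hdr <- c(sprintf("ncols %d", s$ncols),
           sprintf("nrows %d", s$nrows),
           sprintf("xllcorner %.17g", s$origin_x),
           sprintf("yllcorner %.17g", s$origin_y),
           sprintf("cellsize %.17g", s$cellsize),
           sprintf("NODATA_value %.17g", s$nodata))
  m <- r$values[s$nrows:1, , drop = FALSE]   # write north-up
  m[is.na(m)] <- s$nodata
  body <- apply(m, 1L, function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
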