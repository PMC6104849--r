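#' Read a point cloud from XYZ text
#'
#' Reads whitespace- or comma-separated `x y z` triples (a LiDAR-style point
#' cloud exported as text). A single non-numeric first line is treated as a
#' header and skipped.
#'
#' @param path File path.
#' @return A data.frame with numeric columns `x`, `y`, `z`.
#' @export
read_xyz <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  probe <- strsplit(trimws(first), if (sep == ",") "," else "\\s+")[[1]]
  skip <- if (suppressWarnings(anyNA(as.numeric(probe[1])))) 1L else 0L
  df <- utils::read.table(path, sep = sep, skip = skip,
                          col.names = c("x", "y", "z"),
                          colClasses = "numeric")
  df
}

#' Write a point cloud as XYZ text
#'
#' @param cloud A data.frame with columns `x`, `y`, `z`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path) {
  writeLines(sprintf("%.17g %.17g %.17g", cloud$x, cloud$y, cloud$z), path)
  invisible(path)
}

#' Bin a point cloud to a digital surface model
#'
#' Grids a point cloud by taking the maximum elevation of the points falling
#' in each cell, after discarding points above a noise cap `z_cap`
#' (high-noise returns are removed, not clamped). Cell membership uses
#' half-open intervals `[x0, x0 + cellsize)` with the grid origin at the
#' lower-left corner. Cells receiving no surviving point are `NA`.
#'
#' @param cloud Data.frame with columns `x`, `y`, `z` (projected m).
#' @param spec A [grid_spec()].
#' @param z_cap Upper elevation bound (m); points with `z > z_cap` are
#'   discarded before the per-cell maximum. Default 300 m.
#' @return A [ces_raster()] DSM. Attributes `n_rejected` (non-finite
#'   records, reported via a warning), `n_outside` (points off the grid) and
#'   `n_capped` (points above `z_cap`) carry the filtering counts.
#' @examples
#' spec <- grid_spec(0, 0, 1, 2, 2)
#' pts <- data.frame(x = c(0.5, 0.5, 0.5), y = 0.5, z = c(2, 5, 301))
#' bin_points(pts, spec, z_cap = 300)$values[1, 1]  # 5: the 301 m return is noise
#' @export
bin_points <- function(cloud, spec, z_cap = 300) {
  stopifnot(inherits(spec, "grid_spec"), z_cap > 0)
  x <- as.numeric(cloud$x); y <- as.numeric(cloud$y); z <- as.numeric(cloud$z)
  bad <- !is.finite(x) | !is.finite(y) | !is.finite(z)
  n_rejected <- sum(bad)
  if (n_rejected > 0) {
    warning(sprintf("rejected %d record(s) with non-finite coordinates", n_rejected))
    x <- x[!bad]; y <- y[!bad]; z <- z[!bad]
  }
  capped <- z > z_cap
  n_capped <- sum(capped)
  x <- x[!capped]; y <- y[!capped]; z <- z[!capped]
  rc <- point_cell(spec, x, y)
  outside <- is.na(rc$row)
  n_outside <- sum(outside)
  m <- matrix(NA_real_, spec$nrows, spec$ncols)
  if (any(!outside)) {
    idx <- (rc$col[!outside] - 1L) * spec$nrows + rc$row[!outside]
    zz <- z[!outside]
    o <- order(idx, zz)                      # per-cell max = last of each run
    last <- !duplicated(idx[o], fromLast = TRUE)
    m[idx[o][last]] <- zz[o][last]
  }
  out <- ces_raster(spec, m)
  attr(out, "n_rejected") <- n_rejected
  attr(out, "n_outside") <- n_outside
  attr(out, "n_capped") <- n_capped
  out
}

#' Terrain slope in degrees (Horn's method)
#'
#' Computes slope from a surface raster with Horn's 3x3 finite-difference
#' kernel; border cells use edge replication. Cells whose 3x3 window touches
#' nodata are nodata in the output.
#'
#' @param dem A [ces_raster()] of elevations (m), at least 3x3.
#' @return A [ces_raster()] of slope in degrees, in `[0, 90)`.
#' @export
slope_degrees <- function(dem) {
  stopifnot(inherits(dem, "ces_raster"))
  s <- dem$spec
  if (s$nrows < 3 || s$ncols < 3) stop("slope needs a grid of at least 3x3 cells")
  z <- dem$values
  # pad by edge replication; row nrows+2 is the northern edge
  zp <- rbind(z[1, ], z, z[s$nrows, ])
  zp <- cbind(zp[, 1], zp, zp[, s$ncols])
  r <- 2:(s$nrows + 1); cl <- 2:(s$ncols + 1)
  NW <- zp[r + 1, cl - 1]; N <- zp[r + 1, cl]; NE <- zp[r + 1, cl + 1]
  W  <- zp[r, cl - 1];                         E <- zp[r, cl + 1]
  SW <- zp[r - 1, cl - 1]; S <- zp[r - 1, cl]; SE <- zp[r - 1, cl + 1]
  gx <- ((NE + 2 * E + SE) - (NW + 2 * W + SW)) / (8 * s$cellsize)
  gy <- ((NE + 2 * N + NW) - (SE + 2 * S + SW)) / (8 * s$cellsize)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  slope[is.na(z)] <- NA_real_   # no slope at nodata cells
  ces_raster(s, slope)
}

#' Fill nodata cells
#'
#' @param grid A [ces_raster()].
#' @param policy `"none"` returns the input unchanged; `"nearest"` replaces
#'   each nodata cell with the value of the nearest non-nodata cell
#'   (centre-to-centre Euclidean distance; ties broken toward the smaller
#'   row, then the smaller column).
#' @return A [ces_raster()].
#' @export
fill_nodata <- function(grid, policy = c("none", "nearest")) {
  policy <- match.arg(policy)
  if (policy == "none") return(grid)
  m <- grid$values
  holes <- which(is.na(m))
  if (length(holes) == 0) return(grid)
  filled <- which(!is.na(m))
  if (length(filled) == 0) stop("cannot fill an all-nodata grid")
  nr <- grid$spec$nrows
  fr <- ((filled - 1L) %% nr) + 1L
  fc <- ((filled - 1L) %/% nr) + 1L
  for (h in holes) {
    hr <- ((h - 1L) %% nr) + 1L
    hc <- ((h - 1L) %/% nr) + 1L
    d2 <- (fr - hr)^2 + (fc - hc)^2
    cand <- which(d2 == min(d2))
    cand <- cand[order(fr[cand], fc[cand])][1]
    m[h] <- m[filled[cand]]
  }
  ces_raster(grid$spec, m)
}
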