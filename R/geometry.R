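#' Vector feature layers
#'
#' Minimal planar feature containers used for coastlines, shorelines, trails,
#' parks and attraction points. All coordinates are projected metres in the
#' same CRS as the rasters; no on-the-fly reprojection is performed.
#'
#' @param xy For `layer_points`, an n x 2 matrix (or data.frame) of x, y.
#' @param coords For `layer_lines` / `layer_polygons`, a list of n_i x 2
#'   matrices: open polylines for lines, rings for polygons (closure is
#'   implicit; a repeated final vertex is dropped).
#' @return An object of class `ces_layer` with fields `type` and `geoms`.
#' @export
layer_points <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, all(is.finite(xy)))
  structure(list(type = "points", geoms = unname(xy)), class = "ces_layer")
}

#' @rdname layer_points
#' @export
layer_lines <- function(coords) {
  coords <- lapply(coords, function(m) {
    m <- unname(as.matrix(m))
    stopifnot(ncol(m) == 2, nrow(m) >= 2, all(is.finite(m)))
    m
  })
  structure(list(type = "lines", geoms = coords), class = "ces_layer")
}

#' @rdname layer_points
#' @export
layer_polygons <- function(coords) {
  coords <- lapply(coords, function(m) {
    m <- unname(as.matrix(m))
    if (nrow(m) >= 2 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    stopifnot(ncol(m) == 2, nrow(m) >= 3, all(is.finite(m)))
    m
  })
  structure(list(type = "polygons", geoms = coords), class = "ces_layer")
}

#' @export
print.ces_layer <- function(x, ...) {
  n <- if (x$type == "points") nrow(x$geoms) else length(x$geoms)
  cat(sprintf("<ces_layer> %s, %d feature(s)\n", x$type, n))
  invisible(x)
}

n_features <- function(layer) {
  if (layer$type == "points") nrow(layer$geoms) else length(layer$geoms)
}

# All edges of a lines/polygons layer as a matrix (x1, y1, x2, y2).
layer_segments <- function(layer) {
  polys <- layer$type == "polygons"
  segs <- lapply(layer$geoms, function(m) {
    v <- if (polys) rbind(m, m[1, ]) else m
    cbind(v[-nrow(v), 1], v[-nrow(v), 2], v[-1, 1], v[-1, 2])
  })
  do.call(rbind, segs)
}

# Min distance from each (px, py) to a segment set; vectorised over points.
dist_point_segments <- function(px, py, segs) {
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(segs))) {
    x1 <- segs[i, 1]; y1 <- segs[i, 2]; x2 <- segs[i, 3]; y2 <- segs[i, 4]
    vx <- x2 - x1; vy <- y2 - y1
    len2 <- vx * vx + vy * vy
    t <- if (len2 > 0) pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / len2)) else 0
    dx <- px - (x1 + t * vx); dy <- py - (y1 + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# Even-odd ray casting; returns logical vector. Edge points are resolved by
# the half-open comparison below (deterministic, not geometrically special).
point_in_ring <- function(px, py, ring) {
  inside <- rep(FALSE, length(px))
  n <- nrow(ring)
  j <- n
  for (k in seq_len(n)) {
    xj <- ring[j, 1]; yj <- ring[j, 2]; xk <- ring[k, 1]; yk <- ring[k, 2]
    crosses <- ((yk > py) != (yj > py)) &
      (px < (xj - xk) * (py - yk) / (yj - yk) + xk)
    inside <- xor(inside, crosses)
    j <- k
  }
  inside
}

point_in_layer <- function(px, py, layer) {
  stopifnot(layer$type == "polygons")
  inside <- rep(FALSE, length(px))
  for (ring in layer$geoms) inside <- inside | point_in_ring(px, py, ring)
  inside
}

#' Euclidean distance from cell centres to the nearest feature
#'
#' Distances are measured in projected metres from each cell centre.
#' For polygon layers, cells whose centre lies inside a polygon are at
#' distance 0; outside cells measure to the nearest boundary edge.
#'
#' @param spec A [grid_spec()].
#' @param layer A `ces_layer`.
#' @return A [ces_raster()] of distances (m).
#' @export
distance_raster <- function(spec, layer) {
  stopifnot(inherits(layer, "ces_layer"))
  if (n_features(layer) == 0) stop("layer has no features")
  cc <- cell_centers(spec)
  px <- rep(cc$x, each = spec$nrows)
  py <- rep(cc$y, times = spec$ncols)
  if (layer$type == "points") {
    d2 <- rep(Inf, length(px))
    for (i in seq_len(nrow(layer$geoms))) {
      dx <- px - layer$geoms[i, 1]; dy <- py - layer$geoms[i, 2]
      d2 <- pmin(d2, dx * dx + dy * dy)
    }
    d <- sqrt(d2)
  } else {
    d <- dist_point_segments(px, py, layer_segments(layer))
    if (layer$type == "polygons") d[point_in_layer(px, py, layer)] <- 0
  }
  ces_raster(spec, matrix(d, spec$nrows, spec$ncols))
}

#' Rasterise polygon membership of cell centres
#'
#' @param spec A [grid_spec()].
#' @param layer A polygon `ces_layer`.
#' @return A 0/1 [ces_raster()]: 1 where the cell centre falls inside any
#'   polygon.
#' @export
polygon_mask <- function(spec, layer) {
  cc <- cell_centers(spec)
  px <- rep(cc$x, each = spec$nrows)
  py <- rep(cc$y, times = spec$ncols)
  ces_raster(spec, matrix(as.numeric(point_in_layer(px, py, layer)),
                          spec$nrows, spec$ncols))
}
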