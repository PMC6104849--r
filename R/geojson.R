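#' Read a vector layer from GeoJSON
#'
#' Supports FeatureCollections of Point, MultiPoint, LineString,
#' MultiLineString, Polygon and MultiPolygon geometries (outer rings only;
#' holes are not supported). All features in one file must share one
#' geometry family, matching the package's single-type layers.
#'
#' @param path GeoJSON file path.
#' @return A `ces_layer`.
#' @export
read_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(g$type, "FeatureCollection")) g$features else list(g)
  pts <- list(); lns <- list(); pols <- list()
  as_mat <- function(coords)
    do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  for (f in feats) {
    geom <- if (identical(f$type, "Feature")) f$geometry else f
    cs <- geom$coordinates
    switch(geom$type,
      Point = { pts[[length(pts) + 1]] <- c(cs[[1]], cs[[2]]) },
      MultiPoint = for (p in cs) pts[[length(pts) + 1]] <- c(p[[1]], p[[2]]),
      LineString = { lns[[length(lns) + 1]] <- as_mat(cs) },
      MultiLineString = for (l in cs) lns[[length(lns) + 1]] <- as_mat(l),
      Polygon = { pols[[length(pols) + 1]] <- as_mat(cs[[1]]) },
      MultiPolygon = for (p in cs) pols[[length(pols) + 1]] <- as_mat(p[[1]]),
      stop("unsupported GeoJSON geometry: ", geom$type))
  }
  kinds <- c(points = length(pts) > 0, lines = length(lns) > 0,
             polygons = length(pols) > 0)
  if (sum(kinds) != 1) stop("GeoJSON file must contain exactly one geometry family")
  if (kinds["points"]) layer_points(do.call(rbind, pts))
  else if (kinds["lines"]) layer_lines(lns)
  else layer_polygons(pols)
}

#' Write a vector layer to GeoJSON
#'
#' @param layer A `ces_layer`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(layer, path) {
  stopifnot(inherits(layer, "ces_layer"))
  coord_list <- function(m) lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  feats <- switch(layer$type,
    points = lapply(seq_len(nrow(layer$geoms)), function(i) {
      list(type = "Feature", properties = list(id = i),
           geometry = list(type = "Point",
                           coordinates = c(layer$geoms[i, 1], layer$geoms[i, 2])))
    }),
    lines = lapply(seq_along(layer$geoms), function(i) {
      list(type = "Feature", properties = list(id = i),
           geometry = list(type = "LineString",
                           coordinates = coord_list(layer$geoms[[i]])))
    }),
    polygons = lapply(seq_along(layer$geoms), function(i) {
      ring <- rbind(layer$geoms[[i]], layer$geoms[[i]][1, ])  # closed ring
      list(type = "Feature", properties = list(id = i),
           geometry = list(type = "Polygon", coordinates = list(coord_list(ring))))
    }))
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
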