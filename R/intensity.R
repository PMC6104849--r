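#' Nearest-neighbour resampling onto a target grid
#'
#' Looks up, for each target cell centre, the value of the source cell
#' containing that centre. Intended for categorical rasters (e.g. a 30 m
#' land-cover product onto a 6.096 m DSM grid), where averaging would be
#' meaningless. Target centres outside the source extent become `NA`.
#'
#' @param r Source [ces_raster()].
#' @param spec Target [grid_spec()].
#' @return A [ces_raster()] on `spec`.
#' @export
resample_nearest <- function(r, spec) {
  if (spec_identical(r$spec, spec)) return(ces_raster(spec, r$values))
  cc <- cell_centers(spec)
  px <- rep(cc$x, each = spec$nrows)
  py <- rep(cc$y, times = spec$ncols)
  rc <- point_cell(r$spec, px, py)
  v <- rep(NA_real_, length(px))
  ok <- !is.na(rc$row)
  v[ok] <- r$values[cbind(rc$row[ok], rc$col[ok])]
  ces_raster(spec, matrix(v, spec$nrows, spec$ncols))
}

#' Accumulate viewsheds into a viewshed-intensity raster
#'
#' Overlays per-photo visibility masks: each cell of the result counts how
#' many viewsheds cover it. Overlap marks the locations that experience
#' relatively more views — the response variable of the intensity model.
#'
#' @param viewsheds A list of `ces_viewshed` objects, all aligned to `spec`.
#' @param spec The shared [grid_spec()].
#' @param ids Optional photo ids used in error messages (default positions).
#' @return A [ces_raster()] of integer counts. The sum over cells equals
#'   the sum of the viewsheds' `visible_count`s (conservation).
#' @export
accumulate <- function(viewsheds, spec, ids = seq_along(viewsheds)) {
  stopifnot(inherits(spec, "grid_spec"))
  counts <- matrix(0, spec$nrows, spec$ncols)
  for (i in seq_along(viewsheds)) {
    vs <- viewsheds[[i]]
    if (!inherits(vs, "ces_viewshed") || !spec_identical(vs$spec, spec) ||
        !all(dim(vs$mask) == c(spec$nrows, spec$ncols)))
      stop("viewshed for photo id ", ids[i], " is not aligned to the target grid")
    counts <- counts + vs$mask
  }
  ces_raster(spec, counts)
}

#' Land-cover composition of one viewshed
#'
#' @param vs A `ces_viewshed`.
#' @param landcover A categorical [ces_raster()] aligned to the viewshed's
#'   grid (resample first with [resample_nearest()] if needed).
#' @return A named numeric vector of fractions per land-cover class code,
#'   over the visible cells with non-nodata land cover; sums to 1.
#' @export
composition <- function(vs, landcover) {
  stopifnot(inherits(vs, "ces_viewshed"), inherits(landcover, "ces_raster"))
  if (!spec_identical(vs$spec, landcover$spec))
    stop("landcover raster is not aligned to the viewshed grid")
  cls <- landcover$values[vs$mask]
  cls <- cls[!is.na(cls)]
  if (length(cls) == 0) stop("viewshed has no visible cells with land-cover data")
  tab <- table(cls)
  stats::setNames(as.numeric(tab) / length(cls), names(tab))
}

#' Summarise viewshed land-cover composition
#'
#' Per-class mean percentage and standard deviation across viewsheds, in the
#' style of a composition table. Classes absent from a viewshed contribute
#' 0% to that viewshed's entry.
#'
#' @param records A list of composition vectors from [composition()].
#' @param population_sd If `TRUE` use the population SD (divide by n);
#'   default `FALSE` (sample SD). With a single record the sample SD is
#'   reported as 0 by convention (with a message).
#' @return A data.frame with columns `class`, `mean_pct`, `sd_pct`, sorted
#'   by decreasing mean.
#' @export
composition_summary <- function(records, population_sd = FALSE) {
  if (length(records) == 0) stop("no composition records")
  classes <- sort(unique(unlist(lapply(records, names))))
  m <- t(vapply(records, function(r) {
    out <- stats::setNames(numeric(length(classes)), classes)
    out[names(r)] <- r
    out
  }, numeric(length(classes))))
  n <- nrow(m)
  means <- colMeans(m) * 100
  if (n == 1) {
    message("single viewshed: standard deviation reported as 0")
    sds <- rep(0, length(classes))
  } else if (population_sd) {
    sds <- apply(m, 2, function(v) sqrt(mean((v - mean(v))^2))) * 100
  } else {
    sds <- apply(m, 2, stats::sd) * 100
  }
  out <- data.frame(class = classes, mean_pct = unname(means),
                    sd_pct = unname(sds))
  out[order(-out$mean_pct), , drop = FALSE]
}
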