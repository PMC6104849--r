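#' Observer specification for viewshed analysis
#'
#' @param x,y Observer coordinates (projected m); must fall inside the grid
#'   extent of the DSM the observer is used with.
#' @param eye_height Height of the eye above the surface model (m).
#'   Default 1.6 m, a standing adult.
#' @param max_range Maximum viewing distance (m), centre-to-centre and
#'   inclusive. Default 3000 m.
#' @return An object of class `observer_spec`.
#' @export
observer_spec <- function(x, y, eye_height = 1.6, max_range = 3000) {
  stopifnot(is.finite(x), is.finite(y), eye_height > 0, max_range > 0)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 eye_height = as.numeric(eye_height),
                 max_range = as.numeric(max_range)),
            class = "observer_spec")
}

snap_observer <- function(dsm, obs) {
  rc <- point_cell(dsm$spec, obs$x, obs$y)
  if (is.na(rc$row))
    stop("observer falls outside the grid extent")
  if (is.na(dsm$values[rc$row, rc$col]))
    stop("observer cell is nodata; consider fill_nodata(dsm, \"nearest\")")
  c(row = rc$row, col = rc$col)
}

# Shared sight-line arithmetic. The compiled engine in src/viewshed.cpp
# mirrors these expressions exactly; do not "simplify" one without the other.
los_one <- function(z, spec, r0, c0, zo, rt, ct, tan_t, d) {
  step <- spec$cellsize / 2
  K <- floor(d / step)
  while (K >= 1 && K * step >= d) K <- K - 1
  while ((K + 1) * step < d) K <- K + 1
  if (K < 1) return(TRUE)
  k <- seq_len(K)
  s <- k * step
  f <- s / d
  dx <- (ct - c0) * spec$cellsize
  dy <- (rt - r0) * spec$cellsize
  px <- (spec$origin_x + (c0 - 0.5) * spec$cellsize) + dx * f
  py <- (spec$origin_y + (r0 - 0.5) * spec$cellsize) + dy * f
  sc <- floor((px - spec$origin_x) / spec$cellsize) + 1
  sr <- floor((py - spec$origin_y) / spec$cellsize) + 1
  keep <- sr >= 1 & sr <= spec$nrows & sc >= 1 & sc <= spec$ncols &
    !(sr == r0 & sc == c0) & !(sr == rt & sc == ct)
  if (!any(keep)) return(TRUE)
  zs <- z[cbind(sr[keep], sc[keep])]
  s <- s[keep]
  ok <- !is.na(zs)                 # nodata samples neither occlude nor show
  if (!any(ok)) return(TRUE)
  max((zs[ok] - zo) / s[ok]) <= tan_t
}

#' Line of sight between the observer and one target cell
#'
#' Implements the package's normative sight-line semantics: the observer's
#' eye sits `eye_height` above the surface model at the observer cell's
#' value; the segment between the observer and target cell centres is
#' sampled every half cell (samples inside the observer or target cell are
#' excluded); terrain under a sample is the value of the containing cell;
#' the target is visible iff no sample's elevation tangent exceeds the
#' target's tangent (ties are visible — grazing rays pass). Nodata samples
#' neither occlude nor are visible as targets.
#'
#' @param dsm A [ces_raster()] surface model.
#' @param obs An [observer_spec()].
#' @param target Integer `c(row, col)` of the target cell.
#' @return `TRUE` if the target cell is visible.
#' @export
line_of_sight <- function(dsm, obs, target) {
  rc <- snap_observer(dsm, obs)
  rt <- as.integer(target[1]); ct <- as.integer(target[2])
  stopifnot(rt >= 1, rt <= dsm$spec$nrows, ct >= 1, ct <= dsm$spec$ncols)
  cs <- dsm$spec$cellsize
  dx <- (ct - rc["col"]) * cs
  dy <- (rt - rc["row"]) * cs
  d <- sqrt(dx * dx + dy * dy)
  if (d > obs$max_range)
    stop("target cell is beyond max_range")
  if (rt == rc["row"] && ct == rc["col"]) return(TRUE)
  zt <- dsm$values[rt, ct]
  if (is.na(zt)) return(FALSE)
  zo <- dsm$values[rc["row"], rc["col"]] + obs$eye_height
  los_one(dsm$values, dsm$spec, rc["row"], rc["col"], zo, rt, ct,
          (zt - zo) / d, d)
}

as_viewshed_result <- function(dsm, rc, mask) {
  mask[rc["row"], rc["col"]] <- TRUE
  cnt <- sum(mask)
  structure(list(observer_cell = c(row = unname(rc["row"]), col = unname(rc["col"])),
                 mask = mask, visible_count = cnt,
                 visible_area = cnt * dsm$spec$cellsize^2,
                 spec = dsm$spec),
            class = "ces_viewshed")
}

#' @export
print.ces_viewshed <- function(x, ...) {
  cat(sprintf("<ces_viewshed> observer (%d, %d), %d visible cells (%.6g m^2)\n",
              x$observer_cell["row"], x$observer_cell["col"],
              x$visible_count, x$visible_area))
  invisible(x)
}

#' Compute a viewshed (compiled engine)
#'
#' Evaluates [line_of_sight()] for every cell within `max_range` of the
#' observer and returns the boolean visibility mask, using a compiled
#' scan that reproduces the reference semantics exactly (see
#' [viewshed_naive()] for the plain-R oracle).
#'
#' @inheritParams line_of_sight
#' @return A `ces_viewshed`: `observer_cell`, logical `mask` aligned to the
#'   DSM, `visible_count` and `visible_area` (m^2).
#' @export
viewshed <- function(dsm, obs) {
  rc <- snap_observer(dsm, obs)
  mask <- viewshed_cpp(dsm$values, dsm$spec$origin_x, dsm$spec$origin_y,
                       dsm$spec$cellsize, rc["row"], rc["col"],
                       obs$eye_height, obs$max_range)
  as_viewshed_result(dsm, rc, mask)
}

#' Compute a viewshed (naive per-target reference)
#'
#' A straightforward per-target plain-R implementation of the reference
#' sight-line semantics, intended as the correctness oracle for
#' [viewshed()]; the two must agree on every cell. Practical for small
#' grids (advisory limit ~256 x 256).
#'
#' @inheritParams line_of_sight
#' @return A `ces_viewshed`, identical to the one [viewshed()] returns.
#' @export
viewshed_naive <- function(dsm, obs) {
  rc <- snap_observer(dsm, obs)
  spec <- dsm$spec
  z <- dsm$values
  zo <- z[rc["row"], rc["col"]] + obs$eye_height
  cs <- spec$cellsize
  mask <- matrix(FALSE, spec$nrows, spec$ncols)
  rad <- ceiling(obs$max_range / cs) + 1
  for (rt in max(1, rc["row"] - rad):min(spec$nrows, rc["row"] + rad)) {
    for (ct in max(1, rc["col"] - rad):min(spec$ncols, rc["col"] + rad)) {
      dx <- (ct - rc["col"]) * cs
      dy <- (rt - rc["row"]) * cs
      d <- sqrt(dx * dx + dy * dy)
      if (d > obs$max_range) next
      if (rt == rc["row"] && ct == rc["col"]) { mask[rt, ct] <- TRUE; next }
      zt <- z[rt, ct]
      if (is.na(zt)) next
      mask[rt, ct] <- los_one(z, spec, rc["row"], rc["col"], zo, rt, ct,
                              (zt - zo) / d, d)
    }
  }
  as_viewshed_result(dsm, rc, mask)
}
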