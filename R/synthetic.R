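#' Specification of a synthetic coastal landscape
#'
#' Defines a fully synthetic scene with known ground truth used to exercise
#' the whole pipeline: analytic terrain (a coastal plain rising gently
#' inland, Gaussian hills, optional planted walls, canopy heights on wooded
#' zones), zoned NLCD-style land cover, feature layers (coastline, lake,
#' trails, park, attraction and historical-attraction points), a population
#' surface, and the data-generating coefficients used to place photos.
#'
#' Zone geometry is expressed in fractions of the grid extent so the scene
#' scales with `nrows`/`ncols`. The default is a desk-scale 200 x 200 grid
#' of 6.096 m cells (~1.2 x 1.2 km): small enough for the naive viewshed
#' oracle, rich enough that every covariate of the intensity model varies.
#'
#' @param nrows,ncols Grid dimensions (default 200 x 200).
#' @param cellsize Cell size in metres (default 6.096).
#' @param seed Master seed; every generated artefact is a pure function of
#'   the spec including this seed.
#' @param base_elev Land elevation at the coastline (m).
#' @param inland_rise Elevation gain per metre moving inland (m/m).
#' @param bumps List of Gaussian hills, each `c(fx, fy, height, width)` with
#'   `fx`, `fy` fractions of the extent and height/width in metres. The
#'   defaults place two inland hills and a small lookout knoll at the
#'   park's northern tip.
#' @param walls List of planted walls, each `c(fx1, fy1, fx2, fy2, height)`:
#'   cells within half a cell of the segment are raised by `height` m.
#' @param zone_relief Named vector of net surface offsets (m) applied over
#'   zones: positive for canopy above bare ground (`forest`), negative for
#'   a basin (`woody_wetland`, a low swamp sitting in dead ground behind
#'   the coastal plain's inland rise, hence hidden from shore-level
#'   observers).
#' @param beta_true Named data-generating coefficients on the covariate
#'   schema (missing names default to 0): photo placement weights are
#'   proportional to `exp(x . beta_true)`.
#' @param alpha_true Dispersion of the negative-binomial law used by
#'   [make_counts()].
#' @param n_photos Number of photo locations to draw.
#' @param label_noise Probability that each land-class tag of a photo's
#'   label set is flipped (symmetric noise), in `[0, 0.5)`.
#' @param nonrelevant_rate Expected fraction of photos injected as
#'   non-relevant content (empty label set).
#' @param pts_per_cell LiDAR-style returns sampled per cell.
#' @param z_jitter SD of vertical noise on returns (m).
#' @param noise_rate Rate of high-noise returns (z drawn in 400-600 m,
#'   above the 300 m cap).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(nrows = 200, ncols = 200, cellsize = 6.096,
                           seed = 42,
                           base_elev = 2, inland_rise = 0.006,
                           bumps = list(c(0.12, 0.12, 10, 70),
                                        c(0.20, 0.80, 15, 100),
                                        c(0.755, 0.95, 8, 60)),
                           walls = list(),
                           zone_relief = c(forest = 10, woody_wetland = -5),
                           beta_true = c(ocean = 1.5, woody_wetland = -1,
                                         park = 0.6, log_dist_coast = -0.7),
                           alpha_true = 0.5,
                           n_photos = 2000,
                           label_noise = 0.2,
                           nonrelevant_rate = 0.132,
                           pts_per_cell = 4, z_jitter = 0.05,
                           noise_rate = 5e-4) {
  stopifnot(alpha_true > 0, n_photos >= 1,
            label_noise >= 0, label_noise < 0.5,
            nonrelevant_rate >= 0, nonrelevant_rate < 1)
  full <- stats::setNames(numeric(length(covariate_names)), covariate_names)
  unknown <- setdiff(names(beta_true), covariate_names)
  if (length(unknown) > 0)
    stop("unknown beta_true names: ", paste(unknown, collapse = ", "))
  full[names(beta_true)] <- beta_true
  structure(list(
    grid = grid_spec(0, 0, cellsize, nrows, ncols),
    base_elev = base_elev, inland_rise = inland_rise,
    bumps = bumps, walls = walls, zone_relief = zone_relief,
    beta_true = full, alpha_true = alpha_true,
    n_photos = n_photos, label_noise = label_noise,
    nonrelevant_rate = nonrelevant_rate,
    pts_per_cell = pts_per_cell, z_jitter = z_jitter,
    noise_rate = noise_rate, seed = as.integer(seed)),
    class = "synthetic_spec")
}

covariate_names <- c("forest", "agriculture", "fresh_water", "ocean",
                     "woody_wetland", "emergent_wetland", "urban", "park",
                     "trail", "log_dist_coast", "log_dist_lakeshore",
                     "log_dist_attraction", "log_dist_historical",
                     "slope", "pop_density")

rect_ring <- function(x1, x2, y1, y2)
  rbind(c(x1, y1), c(x2, y1), c(x2, y2), c(x1, y2))

circle_ring <- function(cx, cy, r, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Scene geometry in extent fractions; shared by the zone painter, the
# analytic surface and the feature layers so all stay co-registered.
scene_zones <- function(sspec) {
  W <- sspec$grid$ncols * sspec$grid$cellsize
  H <- sspec$grid$nrows * sspec$grid$cellsize
  coast_x <- 0.82 * W
  list(
    coast_x = coast_x, W = W, H = H,
    zones = list(
      ocean = list(code = 11, contains = function(x, y) x >= coast_x),
      beach = list(code = 31, contains = function(x, y)
        x >= 0.787 * W & x < coast_x),
      lake = list(code = 11, contains = function(x, y)
        (x - 0.25 * W)^2 + (y - 0.65 * H)^2 <= (0.1 * W)^2),
      forest = list(code = 42, contains = function(x, y)
        x >= 0.07 * W & x <= 0.33 * W & y >= 0.05 * H & y <= 0.35 * H),
      agriculture = list(code = 82, contains = function(x, y)
        x >= 0.05 * W & x <= 0.35 * W & y >= 0.40 * H & y <= 0.53 * H),
      urban = list(code = 22, contains = function(x, y)
        x >= 0.49 * W & x <= 0.67 * W & y >= 0.07 * H & y <= 0.25 * H),
      woody_wetland = list(code = 90, contains = function(x, y)
        x >= 0.41 * W & x <= 0.62 * W & y >= 0.57 * H & y <= 0.80 * H),
      emergent_wetland = list(code = 95, contains = function(x, y)
        x >= 0.64 * W & x <= 0.77 * W & y >= 0.39 * H & y <= 0.54 * H)
    ),
    background_code = 71,
    park_rect = c(0.70 * W, 0.81 * W, 0.57 * H, 0.90 * H),
    lake_center = c(0.25 * W, 0.65 * H), lake_r = 0.1 * W,
    trail_lines = list(
      cbind(c(0.74, 0.74) * W, c(0.10, 0.90) * H),
      cbind(c(0.40, 0.78) * W, c(0.30, 0.30) * H)),
    attraction_pts = cbind(c(0.815, 0.815, 0.815) * W,
                           c(0.20, 0.50, 0.75) * H),
    historical_pts = cbind(c(0.56, 0.30) * W, c(0.17, 0.70) * H),
    pop_center = c(0.58 * W, 0.16 * H), pop_sigma = 0.15 * W
  )
}

# Analytic ground-truth surface (the DSM the point cloud is sampled from).
scene_surface <- function(sspec, sc, x, y) {
  z <- ifelse(x >= sc$coast_x, 0,
              sspec$base_elev + sspec$inland_rise * (sc$coast_x - x))
  for (b in sspec$bumps)
    z <- z + b[3] * exp(-((x - b[1] * sc$W)^2 + (y - b[2] * sc$H)^2) /
                          (2 * b[4]^2))
  relief <- sspec$zone_relief
  for (zn in names(relief)) {
    if (is.na(relief[zn]) || relief[zn] == 0) next
    if (is.null(sc$zones[[zn]])) stop("zone_relief names an unknown zone: ", zn)
    z <- z + relief[zn] * sc$zones[[zn]]$contains(x, y)
  }
  for (w in sspec$walls) {
    seg <- matrix(c(w[1] * sc$W, w[2] * sc$H, w[3] * sc$W, w[4] * sc$H), 1)
    z <- z + w[5] * (dist_point_segments(x, y, seg) <= sspec$grid$cellsize / 2)
  }
  z
}

#' Generate the synthetic landscape
#'
#' Produces co-registered inputs for the whole pipeline: a jittered
#' LiDAR-style point cloud sampled from the analytic terrain surface (so
#' [bin_points()] reconstructs the surface within jitter), the zoned
#' land-cover raster, every vector feature layer, a population-density
#' raster and the true surface raster. Byte-identical for equal seeds.
#'
#' @param sspec A [synthetic_spec()].
#' @return A list of class `synthetic_landscape`: `cloud` (data.frame),
#'   `landcover`, `population`, `surface` ([ces_raster()]s), `layers`
#'   (named list of `ces_layer`s plus the rasters, ready for
#'   [build_covariates()] once a `dsm` entry is added), `spec`
#'   (the [grid_spec()]) and `sspec`.
#' @export
make_landscape <- function(sspec) {
  stopifnot(inherits(sspec, "synthetic_spec"))
  spec <- sspec$grid
  sc <- scene_zones(sspec)
  cc <- cell_centers(spec)
  px <- rep(cc$x, each = spec$nrows)
  py <- rep(cc$y, times = spec$ncols)

  # land cover: paint zones, erroring on contradictory overlap
  code <- rep(NA_real_, length(px))
  for (zn in names(sc$zones)) {
    z <- sc$zones[[zn]]
    m <- z$contains(px, py)
    clash <- m & !is.na(code) & code != z$code
    if (any(clash))
      stop("zone '", zn, "' contradicts an earlier zone on ",
           sum(clash), " cell(s)")
    code[m] <- z$code
  }
  code[is.na(code)] <- sc$background_code
  landcover <- ces_raster(spec, matrix(code, spec$nrows, spec$ncols))

  surface <- ces_raster(spec, matrix(scene_surface(sspec, sc, px, py),
                                     spec$nrows, spec$ncols))

  pop <- 5 + 500 * exp(-((px - sc$pop_center[1])^2 +
                           (py - sc$pop_center[2])^2) / (2 * sc$pop_sigma^2))
  population <- ces_raster(spec, matrix(pop, spec$nrows, spec$ncols))

  W <- sc$W; H <- sc$H
  layers <- list(
    landcover = landcover,
    ocean = layer_polygons(list(rect_ring(sc$coast_x, W, 0, H))),
    lakes = layer_polygons(list(circle_ring(sc$lake_center[1],
                                            sc$lake_center[2], sc$lake_r))),
    coastline = layer_lines(list(cbind(c(sc$coast_x, sc$coast_x), c(0, H)))),
    trails = layer_lines(sc$trail_lines),
    parks = layer_polygons(list(rect_ring(sc$park_rect[1], sc$park_rect[2],
                                          sc$park_rect[3], sc$park_rect[4]))),
    attractions = layer_points(sc$attraction_pts),
    historical = layer_points(sc$historical_pts),
    population = population)

  cloud <- withr::with_seed(sspec$seed, {
    n <- spec$nrows * spec$ncols * sspec$pts_per_cell
    x <- rep(px, sspec$pts_per_cell) +
      stats::runif(n, -0.5, 0.5) * spec$cellsize
    y <- rep(py, sspec$pts_per_cell) +
      stats::runif(n, -0.5, 0.5) * spec$cellsize
    # keep jittered points on the grid
    eps <- spec$cellsize * 1e-6
    x <- pmin(pmax(x, 0), W - eps)
    y <- pmin(pmax(y, 0), H - eps)
    z <- scene_surface(sspec, sc, x, y) + stats::rnorm(n, 0, sspec$z_jitter)
    noisy <- stats::runif(n) < sspec$noise_rate
    z[noisy] <- stats::runif(sum(noisy), 400, 600)
    data.frame(x = x, y = y, z = z)
  })

  structure(list(cloud = cloud, landcover = landcover,
                 population = population, surface = surface,
                 layers = layers, spec = spec, sspec = sspec),
            class = "synthetic_landscape")
}

#' Simulate negative-binomial counts from a linear predictor
#'
#' Draws `y_i ~ NB(mean mu_i = exp(x_i . beta), variance mu_i + alpha
#' mu_i^2)` via the gamma-Poisson mixture (the `size = 1/alpha`, `mu`
#' parameterisation of [stats::rnbinom()]).
#'
#' @param X Design matrix (with intercept).
#' @param beta_true Coefficient vector.
#' @param alpha_true Dispersion `> 0`.
#' @param seed Integer seed.
#' @return Integer count vector.
#' @export
make_counts <- function(X, beta_true, alpha_true, seed = 1) {
  stopifnot(alpha_true > 0)
  mu <- exp(pmin(drop(as.matrix(X) %*% beta_true), 30))
  withr::with_seed(seed,
    stats::rnbinom(length(mu), size = 1 / alpha_true, mu = mu))
}

#' Place photos on a synthetic landscape and label their content
#'
#' Draws photo locations with placement weights proportional to
#' `exp(x . beta_true)` evaluated on the true covariate stack, jitters them
#' within their cells, injects non-relevant photos at the configured rate,
#' and (optionally) derives each relevant photo's land-class labels from
#' its true viewshed composition, flipping each tag symmetrically with the
#' configured noise probability. Content-category tags (outdoor activity,
#' monuments, plants/animals, sunset/weather) are added at fixed rates for
#' realism; they do not enter the land-cover agreement analysis.
#'
#' @param ls A `synthetic_landscape` from [make_landscape()].
#' @param label If `FALSE`, skip the (viewshed-based) label generation and
#'   return locations only.
#' @param eye_height,max_range Viewshed parameters used for label truth.
#' @param seed Seed; defaults to the landscape seed + 1.
#' @return A data.frame: `id`, `x`, `y`, `row`, `col`, `relevant`, `labels`
#'   (`";"`-separated tags; empty for non-relevant photos or when
#'   `label = FALSE`).
#' @export
make_photos <- function(ls, label = TRUE, eye_height = 1.6, max_range = 3000,
                        seed = NULL) {
  stopifnot(inherits(ls, "synthetic_landscape"))
  sspec <- ls$sspec
  if (is.null(seed)) seed <- sspec$seed + 1L
  spec <- ls$spec
  layers <- c(ls$layers, list(dsm = ls$surface))
  stack <- covariate_stack(spec, layers)
  eta <- Reduce(`+`, Map(function(m, b) m * b, stack,
                         as.list(sspec$beta_true[names(stack)])))
  w <- exp(eta - max(eta))
  if (all(w == 0)) stop("all placement weights are zero")
  ncell <- spec$nrows * spec$ncols

  photos <- withr::with_seed(seed, {
    ids <- sample.int(ncell, sspec$n_photos, replace = TRUE, prob = as.vector(w))
    rows <- ((ids - 1L) %% spec$nrows) + 1L
    cols <- ((ids - 1L) %/% spec$nrows) + 1L
    cc <- cell_centers(spec)
    x <- cc$x[cols] + stats::runif(sspec$n_photos, -0.499, 0.499) * spec$cellsize
    y <- cc$y[rows] + stats::runif(sspec$n_photos, -0.499, 0.499) * spec$cellsize
    relevant <- stats::runif(sspec$n_photos) >= sspec$nonrelevant_rate
    data.frame(id = sprintf("p%05d", seq_len(sspec$n_photos)),
               x = x, y = y, row = rows, col = cols,
               cell_id = ids, relevant = relevant,
               labels = "", stringsAsFactors = FALSE)
  })
  if (!label) return(photos)

  mapping <- default_class_mapping()
  tags <- sort(unique(mapping$tag))
  truth_cache <- new.env(parent = emptyenv())
  true_tags <- function(cell_id, x, y) {
    key <- as.character(cell_id)
    hit <- truth_cache[[key]]
    if (!is.null(hit)) return(hit)
    vs <- viewshed(ls$surface, observer_spec(x, y, eye_height, max_range))
    comp <- composition(vs, ls$landcover)
    pres <- vapply(tags, function(tg)
      sum(comp[names(comp) %in% as.character(map_codes(mapping, tg))]) > 0,
      logical(1))
    truth_cache[[key]] <- pres
    pres
  }
  content_tags <- c("outdoor_activity", "monument_attraction",
                    "plants_animals", "sunset_weather")
  photos$labels <- withr::with_seed(seed + 1L, {
    vapply(seq_len(nrow(photos)), function(i) {
      if (!photos$relevant[i]) return("")
      pres <- true_tags(photos$cell_id[i], photos$x[i], photos$y[i])
      flip <- stats::runif(length(tags)) < sspec$label_noise
      pres <- xor(pres, flip)
      extra <- content_tags[stats::runif(length(content_tags)) < 0.2]
      paste(c(tags[pres], extra), collapse = ";")
    }, character(1))
  })
  photos
}

#' Write a photo table as CSV
#'
#' @param photos Photo data.frame from [make_photos()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_photos <- function(photos, path) {
  utils::write.csv(photos, path, row.names = FALSE)
  invisible(path)
}

#' Read a photo table from CSV
#'
#' @param path CSV with at least `id`, `x`, `y`; optional `relevant` and
#'   `labels` columns (missing `relevant` defaults to `TRUE`).
#' @return A data.frame.
#' @export
read_photos <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  stopifnot(all(c("id", "x", "y") %in% names(df)))
  if (is.null(df$relevant)) df$relevant <- TRUE
  if (is.null(df$labels)) df$labels <- ""
  df$labels[is.na(df$labels)] <- ""
  df
}
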