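#' Pipeline configuration
#'
#' Collects the tunable parameters of the end-to-end run with the standard
#' defaults: 6.096 m cells, 300 m noise cap, 1.6 m eye height, 3 km view
#' range, a 1% cell sample for the model and a 100 m trail buffer.
#'
#' @param cellsize Cell size (m) of the analysis grid.
#' @param z_cap Noise cap for point binning (m).
#' @param eye_height Observer eye height (m).
#' @param max_range Maximum view range (m).
#' @param fraction Cell sampling fraction for the covariate table.
#' @param trail_buffer Trail-proximity buffer (m).
#' @param fill_policy Nodata policy applied to the binned DSM (`"none"` or
#'   `"nearest"`).
#' @param validation_fraction Fraction of labelled photos entering the
#'   content-agreement validation (the manual-classification subsample).
#' @param min_fraction Visible-fraction threshold for class presence.
#' @param seed Seed for the cell sample, the validation subsample and the
#'   Moran permutation test.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cellsize = 6.096, z_cap = 300, eye_height = 1.6,
                            max_range = 3000, fraction = 0.01,
                            trail_buffer = 100, fill_policy = "none",
                            validation_fraction = 0.1, min_fraction = 0,
                            seed = 1) {
  stopifnot(cellsize > 0, z_cap > 0, eye_height > 0, max_range > 0,
            fraction > 0, fraction <= 1, trail_buffer >= 0,
            validation_fraction > 0, validation_fraction <= 1)
  structure(list(cellsize = cellsize, z_cap = z_cap, eye_height = eye_height,
                 max_range = max_range, fraction = fraction,
                 trail_buffer = trail_buffer, fill_policy = fill_policy,
                 validation_fraction = validation_fraction,
                 min_fraction = min_fraction, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full viewshed-intensity pipeline
#'
#' Executes the stages in order on co-registered inputs: (1) bin the point
#' cloud to a DSM; (2) compute one viewshed per photo (cached per observer
#' cell) and accumulate the viewshed-intensity raster, checking the
#' conservation identity `sum(counts) == sum(visible_counts)`; (3)
#' summarise land-cover composition within viewsheds; (4) validate photo
#' content labels against viewshed-visible land cover (percent agreement
#' and Cohen's kappa) on a seeded subsample of labelled relevant photos;
#' (5) build the covariate table, fit the negative-binomial intensity model
#' and its intercept-only null, and report coefficients, IRRs,
#' standardised estimates, pseudo-R2, VIFs and Moran's I of the residuals.
#'
#' @param cloud Point cloud data.frame (`x`, `y`, `z`).
#' @param photos Photo table (`id`, `x`, `y`, optional `relevant`,
#'   `labels`).
#' @param layers Named layer list as for [build_covariates()], minus `dsm`
#'   (the pipeline adds the DSM it builds).
#' @param spec The analysis [grid_spec()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: writes `dsm.asc`, `intensity.asc`,
#'   `viewsheds.csv`, `covariates.csv`, `report.json` and `manifest.json`.
#' @param mapping Tag-to-code mapping for validation.
#' @return A manifest list with every stage product, per-stage timings,
#'   record counts and the resolved configuration.
#' @export
run_pipeline <- function(cloud, photos, layers, spec,
                         config = pipeline_config(), out_dir = NULL,
                         mapping = default_class_mapping()) {
  stopifnot(inherits(spec, "grid_spec"), inherits(config, "pipeline_config"))
  t0 <- proc.time()[3]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[3]
    timings[stage] <<- t1 - t0
    t0 <<- t1
  }

  # stage 1: DSM
  dsm <- bin_points(cloud, spec, z_cap = config$z_cap)
  dsm <- fill_nodata(dsm, config$fill_policy)
  n_rejected <- attr(dsm, "n_rejected")
  tick("dsm")

  # stage 2: viewsheds + intensity (cached by observer cell)
  rc <- point_cell(spec, photos$x, photos$y)
  if (anyNA(rc$row))
    stop("photo(s) outside the grid extent: ",
         paste(utils::head(photos$id[is.na(rc$row)], 5), collapse = ", "))
  counts <- matrix(0, spec$nrows, spec$ncols)
  cache <- new.env(parent = emptyenv())
  vs_for <- function(i) {
    key <- paste(rc$row[i], rc$col[i])
    vs <- cache[[key]]
    if (is.null(vs)) {
      vs <- viewshed(dsm, observer_spec(photos$x[i], photos$y[i],
                                        config$eye_height, config$max_range))
      cache[[key]] <- vs
    }
    vs
  }
  vsum <- data.frame(id = as.character(photos$id),
                     row = rc$row, col = rc$col,
                     visible_count = NA_integer_,
                     visible_area = NA_real_)
  comp_cache <- new.env(parent = emptyenv())
  comp_records <- vector("list", nrow(photos))
  for (i in seq_len(nrow(photos))) {
    vs <- vs_for(i)
    counts <- counts + vs$mask
    vsum$visible_count[i] <- vs$visible_count
    vsum$visible_area[i] <- vs$visible_area
    key <- paste(rc$row[i], rc$col[i])
    cr <- comp_cache[[key]]
    if (is.null(cr)) {
      cr <- composition(vs, layers$landcover)
      comp_cache[[key]] <- cr
    }
    comp_records[[i]] <- cr
  }
  intensity <- ces_raster(spec, counts)
  conservation <- list(sum_counts = sum(counts),
                       sum_visible = sum(vsum$visible_count))
  conservation$ok <- conservation$sum_counts == conservation$sum_visible
  if (!conservation$ok)
    stop("conservation check failed: intensity sum != sum of visible counts")
  tick("viewsheds")

  # stage 3: composition
  comp_summary <- composition_summary(comp_records)
  tick("composition")

  # stage 4: validation on the labelled, relevant subsample
  relevance <- relevance_summary(photos)
  labs <- photo_tag_list(photos$labels)
  has_land <- vapply(labs, function(v)
    length(intersect(v, unique(mapping$tag))) > 0, logical(1))
  cand <- which(as.logical(photos$relevant) & has_land)
  agreement <- NULL
  if (length(cand) > 0) {
    n_val <- max(1, round(config$validation_fraction * length(cand)))
    val_idx <- withr::with_seed(config$seed + 1L,
                                sort(sample(cand, min(n_val, length(cand)))))
    idx_of <- stats::setNames(val_idx, as.character(photos$id)[val_idx])
    agreement <- agreement_report(
      photos[val_idx, , drop = FALSE],
      function(id) vs_for(idx_of[[id]]),
      layers$landcover, mapping = mapping,
      min_fraction = config$min_fraction)
  }
  tick("validation")

  # stage 5: model
  model_layers <- c(layers, list(dsm = dsm))
  covars <- build_covariates(intensity, model_layers,
                             fraction = config$fraction, seed = config$seed,
                             trail_buffer = config$trail_buffer)
  fit <- fit_nb(covars)
  null_fit <- fit_nb(y = covars$y,
                     X = matrix(1, nrow(covars), 1,
                                dimnames = list(NULL, "(Intercept)")))
  report <- nb_report(fit, null_fit)
  vifs <- vif(fit$X[, -1, drop = FALSE])
  mu <- exp(pmin(pmax(drop(fit$X %*% fit$beta), -30), 30))
  pearson <- (covars$y - mu) / sqrt(mu + fit$alpha * mu^2)
  cc <- cell_centers(spec)
  coords <- cbind(cc$x[covars$col], cc$y[covars$row])
  m_idx <- seq_len(nrow(covars))
  if (length(m_idx) > 2000)
    m_idx <- withr::with_seed(config$seed + 2L, sort(sample(m_idx, 2000)))
  moran <- morans_i(pearson[m_idx], coords[m_idx, , drop = FALSE],
                    seed = config$seed + 3L)
  tick("model")

  manifest <- list(
    config = unclass(config),
    n_photos = nrow(photos), n_rejected_points = n_rejected,
    dsm = dsm, intensity = intensity, viewshed_summary = vsum,
    conservation = conservation,
    composition_summary = comp_summary,
    relevance = relevance, agreement = agreement,
    covariates = covars, fit = fit, null_fit = null_fit, report = report,
    vif = vifs, morans_i = moran,
    timings = timings)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_asc(dsm, file.path(out_dir, "dsm.asc"))
    write_asc(intensity, file.path(out_dir, "intensity.asc"))
    utils::write.csv(vsum, file.path(out_dir, "viewsheds.csv"),
                     row.names = FALSE)
    utils::write.csv(covars, file.path(out_dir, "covariates.csv"),
                     row.names = FALSE)
    jsonlite::write_json(attr(covars, "provenance"),
                         file.path(out_dir, "covariates_provenance.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(
      coefficients = report$table,
      alpha = report$alpha, aic = report$aic,
      r2_mcfadden = report$r2_mcfadden,
      r2_nagelkerke = report$r2_nagelkerke,
      morans_i = moran[c("I", "p_value")],
      vif = vifs), file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    jsonlite::write_json(list(
      config = unclass(config),
      n_photos = nrow(photos),
      conservation = conservation,
      relevance = relevance,
      timings = as.list(timings)), file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA)
  }
  manifest
}
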