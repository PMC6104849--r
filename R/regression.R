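#' Log-distance covariate raster
#'
#' Natural log of the Euclidean distance from each cell centre to the
#' nearest feature, with a small additive offset so that cells on a feature
#' are finite: `ln(dist + epsilon)`. Log transformation weights near
#' proximity heavily, reflecting that photographs cluster at or near
#' features rather than scaling linearly with distance.
#'
#' @param layer A `ces_layer` with at least one feature.
#' @param spec Target [grid_spec()].
#' @param unit_km If `TRUE` distances are expressed in kilometres.
#' @param epsilon Additive offset in the chosen unit; default one cell size.
#' @return A [ces_raster()].
#' @export
log_distance_raster <- function(layer, spec, unit_km = FALSE, epsilon = NULL) {
  d <- distance_raster(spec, layer)$values
  scale <- if (unit_km) 1000 else 1
  if (is.null(epsilon)) epsilon <- spec$cellsize / scale
  stopifnot(epsilon > 0)
  ces_raster(spec, log(d / scale + epsilon))
}

# Rasterise the full covariate schema onto `spec`. `layers` is a named list:
#   landcover (ces_raster, NLCD-style codes), ocean/lakes/parks (polygons),
#   coastline/trails (lines), attractions/historical (points),
#   population (ces_raster), dsm (ces_raster, for slope).
# Returns a named list of numeric matrices.
covariate_stack <- function(spec, layers, trail_buffer = 100) {
  need <- c("landcover", "ocean", "lakes", "coastline", "trails", "parks",
            "attractions", "historical", "population", "dsm")
  missing <- setdiff(need, names(layers))
  if (length(missing) > 0)
    stop("missing layers: ", paste(missing, collapse = ", "))
  lc <- resample_nearest(layers$landcover, spec)$values
  ocean <- polygon_mask(spec, layers$ocean)$values
  ind <- function(codes) (lc %in% codes) + 0
  list(
    forest = matrix(ind(41:43), spec$nrows, spec$ncols),
    agriculture = matrix(ind(c(81, 82)), spec$nrows, spec$ncols),
    fresh_water = matrix((lc %in% 11) & ocean == 0, spec$nrows, spec$ncols) + 0,
    ocean = ocean,
    woody_wetland = matrix(ind(90), spec$nrows, spec$ncols),
    emergent_wetland = matrix(ind(95), spec$nrows, spec$ncols),
    urban = matrix(ind(21:24), spec$nrows, spec$ncols),
    park = polygon_mask(spec, layers$parks)$values,
    trail = (distance_raster(spec, layers$trails)$values <= trail_buffer) + 0,
    log_dist_coast = log_distance_raster(layers$coastline, spec, unit_km = TRUE)$values,
    log_dist_lakeshore = log_distance_raster(layers$lakes, spec, unit_km = TRUE)$values,
    log_dist_attraction = log_distance_raster(layers$attractions, spec, unit_km = TRUE)$values,
    log_dist_historical = log_distance_raster(layers$historical, spec, unit_km = TRUE)$values,
    slope = slope_degrees(layers$dsm)$values,
    pop_density = resample_nearest(layers$population, spec)$values
  )
}

layer_checksum <- function(x) {
  v <- if (inherits(x, "ces_raster")) x$values
       else if (inherits(x, "ces_layer")) unlist(x$geoms)
       else unlist(x)
  v <- as.numeric(v[is.finite(v)])
  sprintf("%d:%.8g", length(v), sum(v))
}

#' Build the covariate table for the intensity model
#'
#' Draws a seeded uniform without-replacement sample of cells and assembles
#' the response (viewshed-intensity count) with the full covariate schema:
#' land-cover class indicators, park and trail-buffer indicators,
#' log-distances to coastline, lake/river shoreline, coastal attractions and
#' historical attractions (km), terrain slope (degrees) and population
#' density.
#'
#' @param intensity An [ces_raster()] of viewshed counts.
#' @param layers Named list of layers; see Details in [covariate_stack()]'s
#'   source: `landcover`, `ocean`, `lakes`, `coastline`, `trails`, `parks`,
#'   `attractions`, `historical`, `population`, `dsm`.
#' @param fraction Sampling fraction of all cells (default 0.01, i.e. a 1%
#'   sample); the sample size is `round(fraction * n_cells)`.
#' @param seed Integer seed; the same seed reproduces the same rows.
#' @param trail_buffer Trail-proximity buffer (m), default 100.
#' @return A data.frame with `cell_id`, `row`, `col`, `y` and the covariate
#'   columns; attribute `provenance` records seed, fraction and layer
#'   checksums.
#' @export
build_covariates <- function(intensity, layers, fraction = 0.01, seed = 1,
                             trail_buffer = 100) {
  stopifnot(inherits(intensity, "ces_raster"), fraction > 0, fraction <= 1)
  spec <- intensity$spec
  stack <- covariate_stack(spec, layers, trail_buffer = trail_buffer)
  ncell <- spec$nrows * spec$ncols
  n <- round(fraction * ncell)
  k <- length(stack)
  if (n < k + 2)
    stop(sprintf("sample of %d cells cannot identify %d covariates plus dispersion",
                 n, k))
  ids <- withr::with_seed(seed, sort(sample.int(ncell, n)))
  rows <- ((ids - 1L) %% spec$nrows) + 1L
  cols <- ((ids - 1L) %/% spec$nrows) + 1L
  out <- data.frame(cell_id = ids, row = rows, col = cols,
                    y = as.integer(round(intensity$values[ids])))
  for (nm in names(stack)) out[[nm]] <- stack[[nm]][ids]
  if (anyNA(out)) {
    n0 <- nrow(out)
    out <- out[stats::complete.cases(out), , drop = FALSE]
    warning(sprintf("dropped %d sampled cell(s) with missing covariates",
                    n0 - nrow(out)))
  }
  attr(out, "provenance") <- list(
    seed = seed, fraction = fraction, trail_buffer = trail_buffer,
    n_cells = ncell, n_sampled = n,
    checksums = vapply(layers, layer_checksum, character(1)))
  out
}

#' Negative-binomial log-likelihood (NB2)
#'
#' Log-likelihood of counts under the negative-binomial model with log link
#' `ln mu = X beta` and variance `mu + alpha mu^2`; the `1/alpha` term
#' models the excess of the variance over the Poisson assumption. All gamma
#' functions are evaluated in log space.
#'
#' @param y Non-negative integer response vector.
#' @param X Design matrix including an intercept column.
#' @param beta Coefficient vector (link scale).
#' @param alpha Dispersion, `> 0`. As `alpha -> 0` the likelihood approaches
#'   the Poisson likelihood.
#' @return The summed log-likelihood (scalar).
#' @export
nb_loglik <- function(y, X, beta, alpha) {
  stopifnot(alpha > 0)
  if (any(y < 0) || any(y != round(y)))
    stop("y must be non-negative integers")
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  mu <- exp(eta)
  inv_a <- 1 / alpha
  sum(lgamma(y + inv_a) - lgamma(y + 1) - lgamma(inv_a) -
        (y + inv_a) * log1p(alpha * mu) + y * (log(alpha) + eta))
}

# One IRLS fit at fixed alpha; Fisher scoring with step halving so the
# deviance (-2 loglik) never increases across accepted iterations.
irls_nb <- function(y, X, alpha, beta0 = NULL, tol = 1e-8, max_iter = 100) {
  p <- ncol(X)
  if (is.null(beta0)) {
    mu <- y + mean(y) * 0.1 + 0.1
    beta <- qr.coef(qr(X), log(mu))
  } else beta <- beta0
  dev <- -2 * nb_loglik(y, X, beta, alpha)
  trace <- dev
  clipped <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    if (any(abs(eta) > 30)) clipped <- TRUE
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    zz <- eta + (y - mu) / mu
    qw <- qr(X * sqrt(w))
    beta_new <- qr.coef(qw, sqrt(w) * zz)
    if (anyNA(beta_new)) stop("singular design in IRLS (rank-deficient X)")
    step <- 1
    repeat {
      cand <- beta + step * (beta_new - beta)
      dev_new <- -2 * nb_loglik(y, X, cand, alpha)
      if (is.finite(dev_new) && dev_new <= dev + 1e-12) break
      step <- step / 2
      if (step < 1e-10) { cand <- beta; dev_new <- dev; break }
    }
    delta <- dev - dev_new
    beta <- cand
    dev <- dev_new
    trace <- c(trace, dev)
    if (delta < tol) {
      if (clipped) warning("linear predictor clipped at +/-30 during IRLS")
      return(list(beta = beta, loglik = -dev / 2, converged = TRUE,
                  iterations = it, deviance_trace = trace))
    }
  }
  stop(paste0("IRLS did not converge in ", max_iter, " iterations; ",
              "deviance trace: ",
              paste(sprintf("%.6g", utils::tail(trace, 6)), collapse = " -> ")))
}

nb_aic <- function(loglik, k) 2 * (k + 2) - 2 * loglik  # k+1 betas + alpha

#' Fit the negative-binomial intensity model with AIC-selected dispersion
#'
#' For each candidate dispersion `alpha` on a log-spaced grid (10^-3 to
#' 10^2, 31 points), maximises the NB2 log-likelihood over `beta` by
#' iteratively reweighted least squares, then refines `alpha` around the
#' AIC-minimising candidate by golden-section search (relative tolerance
#' 10^-4). Standard errors come from the observed information at the
#' optimum.
#'
#' @param table A covariate table from [build_covariates()], or any
#'   data.frame with a `y` column; all columns other than
#'   `cell_id`/`row`/`col`/`y` are used as covariates. Alternatively pass
#'   `y` and `X` directly via the named arguments.
#' @param y,X Optional explicit response and design matrix (with intercept);
#'   used when `table` is `NULL`.
#' @param alpha_grid Candidate dispersion grid.
#' @return An object of class `nb_fit`: `beta`, `alpha`, `loglik`, `aic`,
#'   `std_errors`, `p_values`, `irr` (`exp(beta)`), `vcov`, `alpha_trace`
#'   (grid candidates and their AICs), convergence info, and the data used.
#' @export
fit_nb <- function(table = NULL, y = NULL, X = NULL,
                   alpha_grid = 10^seq(-3, 2, length.out = 31)) {
  if (!is.null(table)) {
    stopifnot(is.data.frame(table), "y" %in% names(table))
    covs <- setdiff(names(table), c("cell_id", "row", "col", "y"))
    y <- table$y
    X <- cbind(`(Intercept)` = 1, as.matrix(table[covs]))
  } else {
    stopifnot(!is.null(y), !is.null(X))
    X <- as.matrix(X)
    if (is.null(colnames(X)))
      colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))
  }
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient; screen covariates (see vif)")
  k <- ncol(X) - 1
  fits <- vector("list", length(alpha_grid))
  beta_warm <- NULL
  for (i in seq_along(alpha_grid)) {
    fits[[i]] <- irls_nb(y, X, alpha_grid[i], beta0 = beta_warm)
    beta_warm <- fits[[i]]$beta
  }
  aics <- vapply(fits, function(f) nb_aic(f$loglik, k), numeric(1))
  best <- which.min(aics)
  alpha_trace <- data.frame(alpha = alpha_grid, aic = aics)

  # golden-section refinement on log(alpha) within the bracketing interval
  lo <- log(alpha_grid[max(1, best - 1)])
  hi <- log(alpha_grid[min(length(alpha_grid), best + 1)])
  obj <- function(la) {
    f <- irls_nb(y, X, exp(la), beta0 = fits[[best]]$beta)
    nb_aic(f$loglik, k)
  }
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- obj(x1); f2 <- obj(x2)
  while ((b - a) > 1e-4) {
    if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1; x1 <- b - gr * (b - a); f1 <- obj(x1) }
    else { a <- x1; x1 <- x2; f1 <- f2; x2 <- a + gr * (b - a); f2 <- obj(x2) }
  }
  alpha_hat <- exp((a + b) / 2)
  final <- irls_nb(y, X, alpha_hat, beta0 = fits[[best]]$beta)
  aic_hat <- nb_aic(final$loglik, k)
  if (aic_hat > min(aics)) {  # keep the better of grid vs refinement
    alpha_hat <- alpha_grid[best]
    final <- fits[[best]]
    aic_hat <- aics[best]
  }
  stopifnot(aic_hat <= min(aics) + 1e-9)

  eta <- pmin(pmax(drop(X %*% final$beta), -30), 30)
  mu <- exp(eta)
  w_obs <- mu * (1 + alpha_hat * y) / (1 + alpha_hat * mu)^2
  info <- crossprod(X * sqrt(w_obs))
  vcov <- tryCatch(solve(info), error = function(e) {
    warning("observed information is singular; using pseudo-inverse")
    ev <- eigen(info, symmetric = TRUE)
    pos <- ev$values > max(ev$values) * 1e-12
    ev$vectors[, pos] %*% diag(1 / ev$values[pos], sum(pos)) %*% t(ev$vectors[, pos])
  })
  se <- sqrt(pmax(diag(vcov), 0))
  zval <- final$beta / se
  structure(list(
    beta = stats::setNames(final$beta, colnames(X)),
    alpha = alpha_hat,
    loglik = final$loglik,
    aic = aic_hat,
    std_errors = stats::setNames(se, colnames(X)),
    p_values = stats::setNames(2 * stats::pnorm(-abs(zval)), colnames(X)),
    irr = stats::setNames(exp(final$beta), colnames(X)),
    vcov = vcov,
    alpha_trace = alpha_trace,
    converged = final$converged,
    iterations = final$iterations,
    deviance_trace = final$deviance_trace,
    n = length(y), k = k, y = y, X = X),
    class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat(sprintf("<nb_fit> n = %d, k = %d, alpha = %.4g, logLik = %.2f, AIC = %.1f\n",
              x$n, x$k, x$alpha, x$loglik, x$aic))
  print(data.frame(estimate = x$beta, std_error = x$std_errors,
                   p_value = x$p_values, irr = x$irr))
  invisible(x)
}

#' Model report: estimates, IRRs, standardised coefficients, pseudo-R2
#'
#' Produces the per-covariate reporting table (estimate, standardised
#' estimate, Wald p-value, incidence-rate ratio `exp(beta)`) and the
#' likelihood-based fit summaries McFadden `1 - lnL1/lnL0` and Nagelkerke
#' `[1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]`. Standardised estimates use the
#' `beta_j * SD(x_j) / SD(y)` scaling on the raw response, the linear-model
#' convention; for a count GLM this is an approximate effect-size ranking.
#'
#' @param fit An `nb_fit` for the full model.
#' @param null An `nb_fit` for the intercept-only model fitted with the same
#'   dispersion-selection procedure (required).
#' @return A list of class `nb_report`: `table` (data.frame, one row per
#'   covariate), `r2_mcfadden`, `r2_nagelkerke`, `aic`, `alpha`, `loglik`.
#' @export
nb_report <- function(fit, null) {
  stopifnot(inherits(fit, "nb_fit"))
  if (missing(null) || !inherits(null, "nb_fit"))
    stop("the intercept-only null fit is required to compute pseudo-R2")
  n <- fit$n
  l1 <- fit$loglik; l0 <- null$loglik
  r2_mcf <- 1 - l1 / l0
  r2_nag <- (1 - exp((2 / n) * (l0 - l1))) / (1 - exp((2 / n) * l0))
  sd_y <- stats::sd(fit$y)
  nms <- names(fit$beta)
  std <- vapply(seq_along(nms), function(j) {
    if (nms[j] == "(Intercept)") return(NA_real_)
    fit$beta[j] * stats::sd(fit$X[, j]) / sd_y
  }, numeric(1))
  tab <- data.frame(term = nms,
                    estimate = unname(fit$beta),
                    std_estimate = std,
                    std_error = unname(fit$std_errors),
                    p_value = unname(fit$p_values),
                    irr = unname(fit$irr))
  structure(list(table = tab, r2_mcfadden = r2_mcf, r2_nagelkerke = r2_nag,
                 aic = fit$aic, alpha = fit$alpha, loglik = l1,
                 loglik_null = l0, n = n),
            class = "nb_report")
}

#' @export
print.nb_report <- function(x, ...) {
  cat(sprintf("NB intensity model: alpha = %.4g, AIC = %.1f\n", x$alpha, x$aic))
  cat(sprintf("McFadden R2 = %.3f, Nagelkerke R2 = %.3f\n",
              x$r2_mcfadden, x$r2_nagelkerke))
  print(x$table, digits = 4)
  invisible(x)
}

#' Incidence-rate ratios from link-scale coefficients
#'
#' @param beta Coefficient(s) on the log-mean scale.
#' @return `exp(beta)`: the multiplicative effect on expected counts.
#' @examples
#' irr(2.2893)  # ~9.9-fold
#' @export
irr <- function(beta) exp(beta)

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing each covariate on the others
#' (with intercept). Perfectly collinear columns report `Inf` rather than
#' erroring.
#'
#' @param X Design matrix; an intercept column (constant) is ignored.
#' @param threshold Flagging threshold (default 10).
#' @return A data.frame with `term`, `vif`, `flagged`.
#' @export
vif <- function(X, threshold = 10) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  Xv <- X[, !const, drop = FALSE]
  if (ncol(Xv) < 2) stop("need at least 2 non-intercept covariates")
  out <- vapply(seq_len(ncol(Xv)), function(j) {
    yj <- Xv[, j]
    Z <- cbind(1, Xv[, -j, drop = FALSE])
    res <- qr.resid(qr(Z), yj)
    ss_tot <- sum((yj - mean(yj))^2)
    r2 <- 1 - sum(res^2) / ss_tot
    if (1 - r2 < 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(term = colnames(Xv), vif = out, flagged = out > threshold)
}

knn_weights <- function(coords, k) {
  n <- nrow(coords)
  stopifnot(n >= k + 1)
  nb <- matrix(0L, n, k)
  chunk <- max(1, floor(2e6 / n))
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(n, start + chunk - 1)
    d2 <- outer(coords[idx, 1], coords[, 1], "-")^2 +
      outer(coords[idx, 2], coords[, 2], "-")^2
    for (ii in seq_along(idx)) {
      o <- order(d2[ii, ], seq_len(n))
      nb[idx[ii], ] <- o[o != idx[ii]][1:k]
    }
  }
  nb
}

#' Moran's I with a permutation test
#'
#' Global spatial autocorrelation of model residuals:
#' `I = (n/W) * sum_ij w_ij z_i z_j / sum_i z_i^2` with row-standardised
#' weights. By default the weights connect each point to its `k_neighbors`
#' nearest neighbours; a custom (pre-row-standardisation) weights matrix may
#' be supplied instead, e.g. rook contiguity on a grid. The p-value comes
#' from a seeded permutation null, two-sided around the expectation
#' `-1/(n-1)`.
#'
#' @param residuals Numeric vector (must not be constant).
#' @param coords n x 2 matrix of point coordinates.
#' @param k_neighbors Number of nearest neighbours (default 8).
#' @param n_permutations Permutation count (default 999).
#' @param seed Seed for the permutation draw.
#' @param weights Optional n x n non-negative weights matrix overriding the
#'   k-NN construction; rows are standardised to sum to 1.
#' @return A list: `I`, `p_value`, `expected` (`-1/(n-1)`), `n`.
#' @export
morans_i <- function(residuals, coords, k_neighbors = 8, n_permutations = 999,
                     seed = 1, weights = NULL) {
  z <- residuals - mean(residuals)
  n <- length(z)
  if (stats::sd(residuals) == 0) stop("residuals are constant")
  if (is.null(weights)) {
    coords <- as.matrix(coords)
    stopifnot(nrow(coords) == n, n >= k_neighbors + 1)
    nb <- knn_weights(coords, k_neighbors)
    lag <- function(zz) rowMeans(matrix(zz[nb], n, k_neighbors))
    # row-standardised k-NN weights sum to W = n, so n/W = 1
    stat <- function(zz) sum(zz * lag(zz)) / sum(zz^2)
  } else {
    stopifnot(nrow(weights) == n, ncol(weights) == n)
    rs <- rowSums(weights)
    ok <- rs > 0
    Wm <- weights
    Wm[ok, ] <- Wm[ok, ] / rs[ok]
    W <- sum(Wm)
    stat <- function(zz) (n / W) * sum(zz * (Wm %*% zz)) / sum(zz^2)
  }
  I_obs <- stat(z)
  e_i <- -1 / (n - 1)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) stat(sample(z)), numeric(1))
  })
  p <- (1 + sum(abs(perm - e_i) >= abs(I_obs - e_i))) / (n_permutations + 1)
  list(I = I_obs, p_value = p, expected = e_i, n = n)
}
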