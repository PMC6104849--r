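test_that("log-distance rasters follow ln(d + epsilon) with unit handling", {
  spec <- grid_spec(0, 0, 6.096, 3, 3)
  # feature on a cell centre -> ln(epsilon) there
  pt <- layer_points(matrix(c(3.048, 3.048), 1))
  r <- log_distance_raster(pt, spec)
  expect_equal(r$values[1, 1], log(6.096))
  # 1000 m away in km units with epsilon = 0.006096
  pt2 <- layer_points(matrix(c(3.048 - 1000, 3.048), 1))
  r2 <- log_distance_raster(pt2, spec, unit_km = TRUE)
  expect_equal(r2$values[1, 1], log(1 + 0.006096))
  expect_error(distance_raster(spec, layer_points(matrix(numeric(0), 0, 2))))
})

test_that("distance rasters match exhaustive nearest-feature search", {
  set.seed(21)
  spec <- grid_spec(0, 0, 5, 12, 12)
  cc <- cell_centers(spec)
  px <- rep(cc$x, each = 12); py <- rep(cc$y, times = 12)
  # points layer
  xy <- cbind(runif(7, 0, 60), runif(7, 0, 60))
  got <- distance_raster(spec, layer_points(xy))$values
  want <- matrix(apply(cbind(px, py), 1, function(p)
    min(sqrt((xy[, 1] - p[1])^2 + (xy[, 2] - p[2])^2))), 12, 12)
  expect_equal(got, want)
  # line layer: brute-force point-to-segment minimisation
  ln <- layer_lines(list(cbind(c(5, 30, 55), c(5, 50, 10))))
  gl <- distance_raster(spec, ln)$values
  seg_d <- function(p, a, b) {
    v <- b - a; t <- max(0, min(1, sum((p - a) * v) / sum(v * v)))
    sqrt(sum((p - a - t * v)^2))
  }
  wl <- matrix(apply(cbind(px, py), 1, function(p)
    min(seg_d(p, c(5, 5), c(30, 50)), seg_d(p, c(30, 50), c(55, 10)))), 12, 12)
  expect_equal(gl, wl)
})

test_that("polygon membership agrees with an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(22)
  # offsets keep every edge clear of cell centres: boundary points are
  # convention-dependent in both implementations
  ring <- cbind(c(10.13, 50.21, 55.07, 30.11, 8.23),
                c(8.17, 12.29, 45.31, 58.11, 40.07))
  spec <- grid_spec(0, 0, 3, 20, 20)
  got <- polygon_mask(spec, layer_polygons(list(ring)))$values
  cc <- cell_centers(spec)
  px <- rep(cc$x, each = 20); py <- rep(cc$y, times = 20)
  oracle <- mgcv::in.out(rbind(ring, ring[1, ]), cbind(px, py))
  expect_equal(as.vector(got) == 1, oracle)
  # inside polygons the distance raster is 0
  d <- distance_raster(spec, layer_polygons(list(ring)))$values
  expect_true(all(d[got == 1] == 0))
  expect_true(all(d[got == 0] > 0))
})

test_that("covariate sampling is seeded, sized and matches geometric oracles", {
  skip_if_not_installed("mgcv")
  sspec <- small_scene_spec(n = 40)
  ls <- make_landscape(sspec)
  intensity <- ces_raster(ls$spec, matrix(rpois(1600, 5), 40, 40))
  layers <- c(ls$layers, list(dsm = ls$surface))
  # fraction 1.0 covers every cell
  all_rows <- build_covariates(intensity, layers, fraction = 1, seed = 3)
  expect_equal(nrow(all_rows), 1600)
  # deterministic sample of round(fraction * N) rows
  a <- build_covariates(intensity, layers, fraction = 0.05, seed = 9)
  b <- build_covariates(intensity, layers, fraction = 0.05, seed = 9)
  expect_equal(nrow(a), 80)
  expect_identical(a, b)
  c2 <- build_covariates(intensity, layers, fraction = 0.05, seed = 10)
  expect_false(identical(a$cell_id, c2$cell_id))
  # provenance header
  prov <- attr(a, "provenance")
  expect_equal(prov$seed, 9)
  expect_true(all(c("fraction", "checksums") %in% names(prov)))
  # geometric oracles on 30 random sampled cells
  set.seed(30)
  rows <- all_rows[sample(nrow(all_rows), 30), ]
  cc <- cell_centers(ls$spec)
  for (i in seq_len(nrow(rows))) {
    x <- cc$x[rows$col[i]]; y <- cc$y[rows$row[i]]
    expect_equal(rows$park[i],
                 as.numeric(mgcv::in.out(rbind(ls$layers$parks$geoms[[1]],
                                               ls$layers$parks$geoms[[1]][1, ]),
                                         matrix(c(x, y), 1))))
    segs <- do.call(rbind, lapply(ls$layers$trails$geoms, function(m)
      cbind(m[-nrow(m), , drop = FALSE], m[-1, , drop = FALSE])))
    dmin <- min(apply(segs, 1, function(s) {
      v <- s[3:4] - s[1:2]
      t <- max(0, min(1, sum((c(x, y) - s[1:2]) * v) / sum(v^2)))
      sqrt(sum((c(x, y) - s[1:2] - t * v)^2))
    }))
    expect_equal(rows$trail[i], as.numeric(dmin <= 100))
    expect_equal(rows$y[i], intensity$values[rows$row[i], rows$col[i]])
  }
  # unidentifiable sample size errors
  expect_error(build_covariates(intensity, layers, fraction = 0.005, seed = 1),
               "identify")
})

test_that("nb_loglik matches its closed forms and limits", {
  # single row, y = 0: loglik = -(1/alpha) ln(1 + alpha mu)
  X1 <- matrix(1, 1, 1)
  for (alpha in c(0.2, 1, 3)) for (b0 in c(-1, 0.5, 2)) {
    expect_equal(nb_loglik(0, X1, b0, alpha),
                 -(1 / alpha) * log(1 + alpha * exp(b0)))
  }
  # Poisson limit on a 50-row fixture
  set.seed(14)
  X <- cbind(1, rnorm(50))
  beta <- c(0.8, 0.4)
  y <- rpois(50, exp(X %*% beta))
  pois <- sum(stats::dpois(y, exp(X %*% beta), log = TRUE))
  expect_equal(nb_loglik(y, X, beta, 1e-8), pois, tolerance = 1e-4)
  # pmf normalisation by direct summation
  mu <- 5; alpha <- 0.5
  pmf <- vapply(0:2000, function(k)
    exp(nb_loglik(k, X1, log(mu), alpha)), numeric(1))
  expect_gte(sum(pmf), 1 - 1e-6)
  expect_lte(sum(pmf), 1 + 1e-12)
  # cross-check the pmf against the base distribution
  expect_equal(pmf[1:20], stats::dnbinom(0:19, size = 1 / alpha, mu = mu),
               tolerance = 1e-12)
  expect_error(nb_loglik(c(1.5, 2), cbind(1, 1), 0, 0.5), "integers")
  expect_error(nb_loglik(c(-1, 2), cbind(1, 1), 0, 0.5), "integers")
})

test_that("fit_nb recovers simulated parameters and agrees with glm.nb", {
  skip_if_not_installed("MASS")
  set.seed(2)
  n <- 2000
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rnorm(n))
  beta <- c(1.0, 0.5, -0.3)
  y <- make_counts(X, beta, 0.5, seed = 23)
  fit <- fit_nb(y = y, X = X)
  expect_true(all(abs(fit$beta - beta) < 3 * fit$std_errors))
  expect_gt(fit$alpha, 0.35); expect_lt(fit$alpha, 0.65)
  # independent oracle: MASS::glm.nb on the same data
  or <- MASS::glm.nb(y ~ x1 + x2, data = data.frame(y = y, X[, -1]))
  expect_equal(unname(fit$beta), unname(coef(or)), tolerance = 1e-4)
  expect_equal(fit$alpha, 1 / or$theta, tolerance = 1e-3)
  # observed-information SEs vs glm.nb's Fisher-information SEs: equal
  # asymptotically, a few percent apart in finite samples
  expect_equal(unname(fit$std_errors),
               unname(summary(or)$coefficients[, 2]), tolerance = 0.05)
  # IRR identity and AIC bookkeeping
  expect_identical(fit$irr, exp(fit$beta))
  expect_equal(fit$aic, 2 * (fit$k + 2) - 2 * fit$loglik)
  # the selected alpha beats every grid candidate
  expect_true(all(fit$aic <= fit$alpha_trace$aic + 1e-9))
  # deviance is non-increasing across accepted IRLS iterations
  expect_true(all(diff(fit$deviance_trace) <= 1e-12))
})

test_that("Poisson-generated data drive alpha to the grid floor", {
  set.seed(3)
  n <- 2000
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- rpois(n, exp(0.5 + 0.4 * X[, 2]))
  fit <- fit_nb(y = y, X = X)
  expect_lt(fit$alpha, 0.05)   # near the 1e-3 grid floor, up to sampling noise
  pois <- glm(y ~ X[, 2], family = poisson)
  expect_equal(unname(fit$beta), unname(coef(pois)), tolerance = 1e-3)
})

test_that("duplicating every row leaves estimates unchanged and doubles the loglik", {
  set.seed(4)
  n <- 400
  x1 <- rnorm(n)
  tab <- data.frame(y = make_counts(cbind(1, x1), c(1, 0.5), 0.6, seed = 6),
                    x1 = x1)
  f1 <- fit_nb(tab)
  f2 <- fit_nb(rbind(tab, tab))
  expect_equal(f2$beta, f1$beta, tolerance = 1e-6)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-5)
})

test_that("model report computes IRRs, standardised estimates and pseudo-R2", {
  # McFadden from stated log-likelihoods
  fake <- function(ll, n) structure(list(loglik = ll, n = n), class = "nb_fit")
  set.seed(7)
  n <- 1500
  X <- cbind(`(Intercept)` = 1, a = rnorm(n), b = rnorm(n))
  y <- make_counts(X, c(1, 0.6, 0), 0.5, seed = 8)
  fit <- fit_nb(y = y, X = X)
  null <- fit_nb(y = y, X = X[, 1, drop = FALSE])
  rep <- nb_report(fit, null)
  expect_equal(rep$r2_mcfadden, 1 - fit$loglik / null$loglik)
  expect_equal(rep$r2_nagelkerke,
               (1 - exp((2 / n) * (null$loglik - fit$loglik))) /
                 (1 - exp((2 / n) * null$loglik)))
  expect_gt(rep$r2_mcfadden, 0); expect_lt(rep$r2_mcfadden, 1)
  # standardised estimate convention beta_j * sd(x_j) / sd(y)
  expect_equal(rep$table$std_estimate[2],
               fit$beta[["a"]] * sd(X[, "a"]) / sd(y))
  expect_identical(rep$table$irr, exp(rep$table$estimate))
  # degenerate: null compared with itself -> both pseudo-R2 exactly 0
  rep0 <- nb_report(null, null)
  expect_equal(rep0$r2_mcfadden, 0)
  expect_equal(rep0$r2_nagelkerke, 0)
  expect_error(nb_report(fit), "null")
  # a 2.2893 coefficient reports as a 9.9-fold incidence-rate ratio
  expect_equal(round(irr(2.2893), 1), 9.9)
})

test_that("VIFs equal the definition and flag exact collinearity as infinite", {
  # orthonormal design (orthogonal to the intercept too) -> all VIF 1
  set.seed(18)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 3), 100, 3))))[, -1]
  expect_equal(vif(q)$vif, rep(1, 3), tolerance = 1e-8)
  # duplicated column -> infinite, flagged, no exception
  X <- cbind(a = rnorm(50), b = rnorm(50))
  Xd <- cbind(X, a2 = X[, 1])
  v <- vif(Xd)
  expect_true(is.infinite(v$vif[v$term == "a"]))
  expect_true(all(v$flagged[is.infinite(v$vif)]))
  # random Gaussian design vs lm()-based recomputation
  set.seed(19)
  Z <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  Z[, 2] <- Z[, 1] * 0.8 + rnorm(200, sd = 0.3)
  got <- vif(Z)
  for (j in 1:4) {
    r2 <- summary(lm(Z[, j] ~ Z[, -j]))$r.squared
    expect_equal(got$vif[j], 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("Moran's I detects structure and is calibrated under the null", {
  # perfect checkerboard with rook weights -> I = -1
  n_side <- 10
  idx <- expand.grid(r = 1:n_side, c = 1:n_side)
  z <- (-1)^(idx$r + idx$c)
  W <- matrix(0, 100, 100)
  for (i in 1:100) for (j in 1:100) {
    if (abs(idx$r[i] - idx$r[j]) + abs(idx$c[i] - idx$c[j]) == 1) W[i, j] <- 1
  }
  m <- morans_i(z, cbind(idx$r, idx$c), weights = W, n_permutations = 99)
  expect_equal(m$I, -1)
  # smooth spatial gradient -> strong positive autocorrelation
  set.seed(25)
  coords <- cbind(runif(400), runif(400))
  grad <- coords[, 1] + coords[, 2] + rnorm(400, sd = 0.05)
  mg <- morans_i(grad, coords, k_neighbors = 8, n_permutations = 999, seed = 2)
  expect_gt(mg$I, 0)
  expect_lte(mg$p_value, 0.01)
  # i.i.d. residuals stay inside the permutation 95% band in >= 90% of replicates
  inside <- 0
  for (s in 1:50) {
    set.seed(1000 + s)
    zz <- rnorm(400)
    cs <- cbind(runif(400), runif(400))
    nbm <- morans_i(zz, cs, k_neighbors = 8, n_permutations = 199, seed = s)
    inside <- inside + (nbm$p_value > 0.05)
  }
  expect_gte(inside, 45)
  expect_error(morans_i(rep(1, 20), cbind(runif(20), runif(20))), "constant")
})
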