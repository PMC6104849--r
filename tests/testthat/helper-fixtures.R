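# Shared fixture builders. Everything is generated in code under fixed
# seeds; nothing is read from disk.

unit_spec <- function(n = 10, cellsize = 1) grid_spec(0, 0, cellsize, n, n)

flat_dsm <- function(n = 41, cellsize = 1, z = 0)
  ces_raster(unit_spec(n, cellsize), matrix(z, n, n))

# white-noise terrain: deliberately rough, the hardest case for sight-line
# agreement between implementations
rough_terrain <- function(seed, n = 64, cellsize = 6.096, base = 3, relief = 2) {
  set.seed(seed)
  ces_raster(grid_spec(0, 0, cellsize, n, n),
             matrix(base + relief * rnorm(n * n), n, n))
}

# smooth correlated terrain (sum of random Gaussian bumps)
smooth_terrain <- function(seed, n = 64, cellsize = 6.096, n_bumps = 6) {
  set.seed(seed)
  cc <- cell_centers(grid_spec(0, 0, cellsize, n, n))
  z <- matrix(2, n, n)
  for (b in seq_len(n_bumps)) {
    cx <- runif(1, 0, n * cellsize); cy <- runif(1, 0, n * cellsize)
    h <- runif(1, 2, 12); w <- runif(1, 3, 10) * cellsize
    z <- z + h * exp(-(outer((cc$y - cy)^2, (cc$x - cx)^2, "+")) / (2 * w^2))
  }
  ces_raster(grid_spec(0, 0, cellsize, n, n), z)
}

random_observer <- function(dsm, max_range = 200, eye = 1.6) {
  s <- dsm$spec
  observer_spec(runif(1, 0.1, 0.9) * s$ncols * s$cellsize,
                runif(1, 0.1, 0.9) * s$nrows * s$cellsize,
                eye, max_range)
}

# tiny synthetic scene for fast end-to-end tests
small_scene_spec <- function(seed = 11, n = 80, n_photos = 250, ...)
  synthetic_spec(nrows = n, ncols = n, seed = seed, n_photos = n_photos, ...)
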