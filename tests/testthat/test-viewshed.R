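# Independent dense-sampling line-of-sight oracle: same nearest-cell lookup
# and tangent rule as the reference semantics, but sampled every cellsize/8.
# Returns the signed decision margin (tan_target - max sample tangent);
# >= 0 means visible.
dense_los_margin <- function(dsm, obs, rt, ct, step_div = 8) {
  s <- dsm$spec; z <- dsm$values
  rc <- unlist(point_cell(s, obs$x, obs$y)); r0 <- rc[1]; c0 <- rc[2]
  zo <- z[r0, c0] + obs$eye_height
  cs <- s$cellsize
  dx <- (ct - c0) * cs; dy <- (rt - r0) * cs
  d <- sqrt(dx^2 + dy^2)
  tan_t <- (z[rt, ct] - zo) / d
  step <- cs / step_div
  ss <- seq(step, d - step / 2, by = step)
  f <- ss / d
  px <- (s$origin_x + (c0 - 0.5) * cs) + dx * f
  py <- (s$origin_y + (r0 - 0.5) * cs) + dy * f
  sc <- floor((px - s$origin_x) / cs) + 1
  sr <- floor((py - s$origin_y) / cs) + 1
  keep <- !(sr == r0 & sc == c0) & !(sr == rt & sc == ct)
  if (!any(keep)) return(Inf)
  zs <- z[cbind(sr[keep], sc[keep])]
  tan_t - max((zs - zo) / ss[keep])
}

test_that("every in-range target is visible on flat terrain", {
  dsm <- flat_dsm(41)
  obs <- observer_spec(20.5, 20.5, 1.6, 10)
  vs <- viewshed(dsm, obs)
  # brute-force lattice-disk oracle
  disk <- sum(outer(1:41, 1:41,
                    function(r, cl) sqrt((r - 21)^2 + (cl - 21)^2) <= 10))
  expect_equal(vs$visible_count, disk)
  expect_true(all(vs$mask[vs$mask] ))
  expect_equal(vs$visible_area, disk * 1)
  # in-range single targets
  expect_true(line_of_sight(dsm, obs, c(21, 31)))
})

test_that("a wall occludes a ground target behind it (analytic tangents)", {
  # ground 0 m, 10 m wall at 100 m, ground target at 200 m, eye 1.6 m:
  # wall tangent (10-1.6)/100 = 0.084 > target tangent -1.6/200 = -0.008
  spec <- grid_spec(0, 0, 1, 3, 301)
  z <- matrix(0, 3, 301); z[2, 101] <- 10
  dsm <- ces_raster(spec, z)
  obs <- observer_spec(0.5, 1.5, 1.6, 3000)
  expect_false(line_of_sight(dsm, obs, c(2, 201)))
  # without the wall the same target is visible
  expect_true(line_of_sight(ces_raster(spec, matrix(0, 3, 301)), obs, c(2, 201)))
  # the wall top itself is visible
  expect_true(line_of_sight(dsm, obs, c(2, 101)))
})

test_that("line_of_sight agrees with a cellsize/8 dense-sampling oracle away from grazing rays", {
  n_checked <- 0; n_agree <- 0
  for (seed in 1:5) {
    dsm <- smooth_terrain(seed)
    set.seed(seed + 100)
    obs <- random_observer(dsm, max_range = 3000)
    rc <- unlist(point_cell(dsm$spec, obs$x, obs$y))
    for (t in 1:20) {
      rt <- sample(64, 1); ct <- sample(64, 1)
      if (rt == rc[1] && ct == rc[2]) next
      got <- line_of_sight(dsm, obs, c(rt, ct))
      margin <- dense_los_margin(dsm, obs, rt, ct)
      n_checked <- n_checked + 1
      if (got == (margin >= 0)) n_agree <- n_agree + 1
      else expect_lt(abs(margin), 0.005)  # disagreement only at grazing rays
    }
  }
  expect_gte(n_agree / n_checked, 0.95)
})

test_that("compiled viewshed agrees exactly with the naive oracle", {
  for (seed in 1:10) {
    dsm <- rough_terrain(seed)
    set.seed(seed + 500)
    obs <- random_observer(dsm, max_range = 200)
    a <- viewshed(dsm, obs)
    b <- viewshed_naive(dsm, obs)
    expect_identical(a$mask, b$mask)
    expect_identical(a$visible_count, b$visible_count)
  }
})

test_that("an 8-neighbour wall ring confines the viewshed per reference semantics", {
  n <- 21
  z <- matrix(0, n, n)
  z[10:12, 10:12] <- 100; z[11, 11] <- 0   # ring of +100 around the observer
  dsm <- ces_raster(unit_spec(n), z)
  obs <- observer_spec(10.5, 10.5, 1.6, 100)
  a <- viewshed(dsm, obs)
  b <- viewshed_naive(dsm, obs)
  expect_identical(a$mask, b$mask)
  expect_true(a$mask[11, 11])
  expect_true(all(a$mask[10:12, 10:12]))   # wall tops are visible
  # ground beyond the ring is hidden
  outside <- a$mask; outside[10:12, 10:12] <- NA
  expect_false(any(outside, na.rm = TRUE))
})

test_that("max_range below the cell size leaves only the observer visible", {
  dsm <- flat_dsm(9)
  vs <- viewshed(dsm, observer_spec(4.5, 4.5, 1.6, 0.5))
  expect_equal(vs$visible_count, 1)
  expect_true(vs$mask[5, 5])
})

test_that("raising the eye never shrinks the visible set", {
  for (seed in 1:5) {
    dsm <- rough_terrain(seed, n = 48)
    set.seed(seed + 900)
    obs_lo <- random_observer(dsm, max_range = 150)
    obs_hi <- observer_spec(obs_lo$x, obs_lo$y, obs_lo$eye_height + 5,
                            obs_lo$max_range)
    lo <- viewshed(dsm, obs_lo)$mask
    hi <- viewshed(dsm, obs_hi)$mask
    expect_true(all(hi[lo]))
  }
})

test_that("shrinking max_range yields a subset mask", {
  for (seed in 1:5) {
    dsm <- rough_terrain(seed, n = 48)
    set.seed(seed + 1300)
    obs <- random_observer(dsm, max_range = 180)
    wide <- viewshed(dsm, obs)$mask
    narrow <- viewshed(dsm, observer_spec(obs$x, obs$y, obs$eye_height, 90))$mask
    expect_true(all(wide[narrow]))
  }
})

test_that("elevation added outside the visible set cannot create visibility within it", {
  dsm <- flat_dsm(41)
  obs <- observer_spec(20.5, 20.5, 1.6, 12)
  base <- viewshed(dsm, obs)$mask
  z <- dsm$values
  z[!base] <- z[!base] + 50      # raise terrain only outside the viewshed
  after <- viewshed(ces_raster(dsm$spec, z), obs)$mask
  expect_identical(after, base)
})

test_that("observer errors are informative", {
  dsm <- flat_dsm(9)
  expect_error(viewshed(dsm, observer_spec(100, 100, 1.6, 10)), "outside")
  z <- dsm$values; z[5, 5] <- NA
  expect_error(viewshed(ces_raster(dsm$spec, z), observer_spec(4.5, 4.5, 1.6, 10)),
               "fill_nodata")
})

test_that("nodata targets are invisible but nodata samples do not occlude", {
  z <- matrix(0, 3, 21)
  z[2, 11] <- NA          # hole between observer and far target
  dsm <- ces_raster(grid_spec(0, 0, 1, 3, 21), z)
  obs <- observer_spec(0.5, 1.5, 1.6, 100)
  expect_false(line_of_sight(dsm, obs, c(2, 11)))  # hole itself not visible
  expect_true(line_of_sight(dsm, obs, c(2, 21)))   # sight passes over the hole
})
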