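test_that("friction is the reciprocal of speed, with road precedence", {
  road <- raster_grid(matrix(c("tarmac", "none", "gravel", "none"), 2), 12.5)
  land <- raster_grid(matrix(c("farmland", "bushland", "bushland", "water"),
                             2), 12.5)
  barrier <- raster_grid(matrix(FALSE, 2, 2), 12.5)
  fr <- build_friction_surface(list(road_class = road, land_cover = land,
                                    barrier_mask = barrier))
  # tarmac at 80 km/h -> 0.045 s/m
  expect_equal(fr$grid$values[1, 1], 0.045)
  # gravel road over bushland: road wins -> 3.6/40 = 0.09 s/m
  expect_equal(fr$grid$values[1, 2], 0.09)
  # walking over bushland at 4 km/h
  expect_equal(fr$grid$values[2, 1], 0.9)
  # water is impassable
  expect_true(fr$impassable[2, 2])
  expect_true(is.na(fr$grid$values[2, 2]))
})

test_that("barrier mask and unmapped classes are handled", {
  road <- raster_grid(matrix("none", 2, 2), 12.5)
  land <- raster_grid(matrix("farmland", 2, 2), 12.5)
  barrier <- raster_grid(matrix(c(TRUE, FALSE, FALSE, FALSE), 2), 12.5)
  fr <- build_friction_surface(list(road_class = road, land_cover = land,
                                    barrier_mask = barrier))
  expect_true(fr$impassable[1, 1])
  land2 <- raster_grid(matrix("lava", 2, 2), 12.5)
  expect_error(build_friction_surface(list(road_class = road,
                                           land_cover = land2,
                                           barrier_mask = barrier)),
               "lava")
})

test_that("uniform-surface travel times follow the stated edge costs", {
  f <- make_friction(matrix(0.72, 7, 7), pixel_size = 12.5)  # walk 5 km/h
  tt <- least_cost_travel_time(f, c(1, 1))
  # 4 rook steps: 4 * 12.5 * 0.72 = 36 s = 0.6 min
  expect_equal(tt$grid$values[1, 5], 0.6)
  # diagonal neighbour: 12.5 * sqrt(2) * 0.72 s
  expect_equal(tt$grid$values[2, 2] * 60, 12.5 * sqrt(2) * 0.72)
  # origin is zero
  expect_equal(tt$grid$values[1, 1], 0)
  # closed form at Chebyshev offset (i, j)
  for (ij in list(c(3, 5), c(4, 2), c(6, 6))) {
    i <- ij[1] - 1; j <- ij[2] - 1
    expect_equal(tt$grid$values[ij[1], ij[2]] * 60,
                 0.72 * 12.5 * (sqrt(2) * min(i, j) + abs(i - j)))
  }
})

test_that("a wall forces the detour the brute-force oracle finds", {
  f <- matrix(0.72, 5, 5)
  f[1:4, 3] <- NA                      # wall with a gap at the bottom
  fs <- make_friction(f, 12.5)
  tt <- least_cost_travel_time(fs, c(1, 1))
  oracle <- bf_travel_time(f, 12.5, origin = 1L)
  expect_equal(tt$grid$values, oracle, tolerance = 1e-12)
  # the detour is strictly longer than the unobstructed path
  free <- least_cost_travel_time(make_friction(matrix(0.72, 5, 5), 12.5),
                                 c(1, 1))
  expect_gt(tt$grid$values[1, 5], free$grid$values[1, 5])
})

test_that("least-cost path equals brute force on random instances", {
  for (s in 1:100) {
    set.seed(s)
    fs <- random_friction(6, 6)
    tt <- least_cost_travel_time(fs, 1L)
    oracle <- bf_travel_time(fs$grid$values, fs$grid$pixel_size, 1L)
    expect_equal(tt$grid$values, oracle, tolerance = 1e-12)
  }
})

test_that("travel time is monotone under friction increase", {
  for (s in 1:20) {
    set.seed(200 + s)
    fs <- random_friction(6, 6, p_block = 0.1)
    tt1 <- least_cost_travel_time(fs, 1L)$grid$values
    f2 <- fs$grid$values
    pick <- sample(which(!is.na(f2)), 1)
    f2[pick] <- f2[pick] * 5
    tt2 <- least_cost_travel_time(make_friction(f2, 12.5), 1L)$grid$values
    both <- !is.na(tt1) & !is.na(tt2)
    expect_true(all(tt2[both] >= tt1[both] - 1e-12))
  }
})

test_that("travel time behaves like a potential: |t(a)-t(b)| <= edge cost", {
  set.seed(77)
  fs <- random_friction(8, 8, p_block = 0.1)
  tt <- least_cost_travel_time(fs, 1L)$grid$values * 60
  f <- fs$grid$values
  px <- fs$grid$pixel_size
  nr <- nrow(f); nc <- ncol(f)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (is.na(tt[r, cc])) next
    for (o in list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))) {
      r2 <- r + o[1]; c2 <- cc + o[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || is.na(tt[r2, c2])) next
      d <- px * if (all(o != 0)) sqrt(2) else 1
      w <- d * (f[r, cc] + f[r2, c2]) / 2
      expect_lte(abs(tt[r, cc] - tt[r2, c2]), w + 1e-9)
    }
  }
})

test_that("impassable origins and unreachable pixels are handled", {
  f <- matrix(0.72, 4, 4)
  f[1, 1] <- NA
  expect_error(least_cost_travel_time(make_friction(f, 12.5), c(1, 1)),
               "impassable")
  # an enclave cut off by NA cells is flagged unreachable, not an error
  f2 <- matrix(0.72, 5, 5)
  f2[4, 4:5] <- NA; f2[5, 3] <- NA; f2[3, 4:5] <- NA; f2[4, 3] <- NA
  tt <- least_cost_travel_time(make_friction(f2, 12.5), c(1, 1))
  expect_true(tt$unreachable[5, 5])
  expect_true(is.na(tt$grid$values[5, 5]))
})

test_that("zonal means average reachable pixels only", {
  mins <- matrix(c(10, 20, 30, NA), 2)   # col-major: [1,1]=10, [2,1]=20 ...
  ttr <- structure(list(grid = raster_grid(mins, 100),
                        unreachable = matrix(c(FALSE, FALSE, FALSE, TRUE), 2),
                        origin = 1L),
                   class = "travel_time_raster")
  tab <- data.frame(ea_id = c("A", "B"), pop_u5 = c(10, 10),
                    ntl = 0, pfpr = 0.3, stringsAsFactors = FALSE)
  eas <- ea_set(tab, pixels = list(A = c(1L, 2L), B = c(3L, 4L)))
  z <- suppressWarnings(zonal_mean_travel_time(ttr, eas))
  expect_equal(z$mean_travel_min, c(15, 30))   # B averages its one
  expect_equal(z$n_pixels, c(2L, 1L))          # reachable pixel only
  # EA with no reachable pixels is flagged with a warning
  eas2 <- ea_set(tab, pixels = list(A = c(1L, 2L), B = 4L))
  expect_warning(z2 <- zonal_mean_travel_time(ttr, eas2), "no reachable")
  expect_true(is.na(z2$mean_travel_min[2]))
  # an EA that contains only the hospital pixel has zero mean
  mins0 <- matrix(c(0, 5, 5, 5), 2)
  ttr0 <- structure(list(grid = raster_grid(mins0, 100),
                         unreachable = matrix(FALSE, 2, 2), origin = 1L),
                    class = "travel_time_raster")
  easH <- ea_set(data.frame(ea_id = "H", pop_u5 = 1, ntl = 0, pfpr = 0.3),
                 pixels = list(H = 1L))
  expect_equal(zonal_mean_travel_time(ttr0, easH)$mean_travel_min, 0)
})

test_that("polygon membership agrees with pixel assignment", {
  land <- generate_landscape(landscape_config(nx = 50, ny = 50,
                                              pixel_size = 100, n_eas = 6,
                                              barrier_frac = 0, seed = 9))
  fr <- build_friction_surface(land$layers)
  tt <- least_cost_travel_time(fr, land$hospital)
  z_pix <- zonal_mean_travel_time(tt, land$eas)
  eas_poly <- ea_set(land$eas$table, polygons = land$eas$polygons)
  z_poly <- zonal_mean_travel_time(tt, eas_poly)
  # convex hulls overlap slightly, so means agree approximately
  expect_equal(z_poly$mean_travel_min, z_pix$mean_travel_min,
               tolerance = 0.25)
})

test_that("travel-time binning uses half-open intervals", {
  expect_equal(bin_travel_time(c(0, 29.99, 30, 59.99, 60, 90, 250)),
               c("<30", "<30", "30-59", "30-59", "60-89", ">=90", ">=90"))
  # the reference median severe travel time of 36 min sits in 30-59
  expect_equal(bin_travel_time(36), "30-59")
  expect_equal(bin_travel_time(c(14.9, 15, 119.9, 120), "15min"),
               c("<15", "15-29", "105-119", ">=120"))
  expect_error(bin_travel_time(-1), "non-negative")
})
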