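test_that("single-source doses reduce to one lattice term", {
  rf <- toy_rf()
  spec <- grid_spec(0, 0, 1, 15, 15, z_edges = c(0, 2))
  zero <- concentration_field(spec, array(0, c(15, 15, 1)))
  gd0 <- surface_deposition(spec, matrix(0, 15, 15))
  expect_equal(max(compute_dose_map(rf, zero, gd0)$values), 0)
  # single ground source of c kBq/m2 at offset (l0, m0): R(l0, m0, 0) * c
  g <- matrix(0, 15, 15); g[10, 6] <- 3.25
  gd <- surface_deposition(spec, g)
  val <- dose_at_cell(8, 8, rf, ground = gd)
  expect_equal(val, rf$ground[2 + rf$half_l + 1, -2 + rf$half_l + 1] * 3.25,
               tolerance = 1e-15)
  # sources outside the lattice support contribute nothing
  expect_identical(dose_at_cell(1, 15, rf, ground = gd), 0)
})

test_that("dose maps equal the naive oracle on random scenes", {
  for (seed in 1:4) {
    sc <- random_scene("plain", seed = seed)
    rf <- toy_rf(seed = seed + 100L)
    m <- compute_dose_map(rf, cloud = sc$cloud, ground = sc$ground)
    set.seed(seed)
    for (q in seq_len(8)) {
      i <- sample(21, 1); j <- sample(21, 1)
      o <- oracle_dose_cell(i, j, rf, sc$cloud, sc$ground)
      expect_equal(m$values[i, j], o, tolerance = 1e-12)
    }
  }
})

test_that("obstacle chords match geometry and the interval oracle", {
  spec <- grid_spec(0, 0, 1, 10, 10, z_edges = c(0, 1, 2, 3))
  none <- obstacle_mask(spec, array(FALSE, c(10, 10, 3)), 1)
  expect_identical(obstacle_chord(c(0.5, 0.5, 0.5), c(9.5, 9.5, 2.5), none), 0)
  # axis-aligned ray through k contiguous 1-m cells
  occ <- array(FALSE, c(10, 10, 3)); occ[4:7, 2, 1] <- TRUE
  mk <- obstacle_mask(spec, occ, 1)
  expect_equal(obstacle_chord(c(0.5, 1.5, 0.5), c(9.5, 1.5, 0.5), mk), 4)
  # 45-degree diagonal through one cell in plan: sqrt(2)
  occ2 <- array(FALSE, c(10, 10, 3)); occ2[5, 5, 1] <- TRUE
  mk2 <- obstacle_mask(spec, occ2, 1)
  d <- obstacle_chord(c(3.5, 3.5, 0.5), c(6.5, 6.5, 0.5), mk2)
  expect_lt(abs(d - sqrt(2)), 1e-9)
  expect_lt(abs(d - oracle_chord(c(3.5, 3.5, 0.5), c(6.5, 6.5, 0.5), mk2)), 1e-9)
  # random oblique rays against the interval oracle
  set.seed(5)
  occ3 <- array(runif(300) < 0.2, c(10, 10, 3))
  mk3 <- obstacle_mask(spec, occ3, 1)
  for (q in 1:25) {
    s <- c(runif(2, 0.2, 9.8), runif(1, 0.1, 2.9))
    t <- c(runif(2, 0.2, 9.8), runif(1, 0.1, 2.9))
    expect_equal(obstacle_chord(s, t, mk3), oracle_chord(s, t, mk3),
                 tolerance = 1e-9)
    # chord never exceeds the separation
    expect_lte(obstacle_chord(s, t, mk3), sqrt(sum((t - s)^2)) + 1e-12)
  }
})

test_that("attenuated doses follow exp(-mu L) and the oracle", {
  # horizontal ray: cloud source at layer-centre 1 m, 2 m of obstacle with
  # mu = 1.85 -> factor exp(-3.7)
  spec <- grid_spec(0, 0, 1, 11, 11, z_edges = c(0, 2))
  cl <- array(0, c(11, 11, 1)); cl[2, 6, 1] <- 1
  cloud <- concentration_field(spec, cl)
  rf <- toy_rf(L = 9L, n_alt = 2L, altitudes = c(1, 5))
  occ <- array(FALSE, c(11, 11, 1)); occ[5:6, 6, 1] <- TRUE
  mask <- obstacle_mask(spec, occ, mu = 1.85)
  free <- dose_at_cell(9, 6, rf, cloud = cloud)
  att <- dose_at_cell_attenuated(9, 6, rf, cloud = cloud, mask = mask)
  expect_equal(att / free, exp(-1.85 * 2), tolerance = 1e-12)
  # mu = 0 mask leaves the map unchanged
  mask0 <- obstacle_mask(spec, occ, mu = 0)
  m0 <- compute_dose_map(rf, cloud = cloud, mask = mask0)
  mf <- compute_dose_map(rf, cloud = cloud)
  keep <- !m0$skipped
  expect_identical(m0$values[keep], mf$values[keep])
  # random masked scenes against the full oracle
  for (seed in 11:13) {
    sc <- random_scene("mask", seed = seed)
    rfs <- toy_rf(seed = seed)
    m <- compute_dose_map(rfs, cloud = sc$cloud, ground = sc$ground,
                          mask = sc$mask)
    set.seed(seed)
    for (q in 1:6) {
      i <- sample(21, 1); j <- sample(21, 1)
      o <- oracle_dose_cell(i, j, rfs, sc$cloud, sc$ground, mask = sc$mask)
      expect_equal(m$values[i, j], o, tolerance = 1e-12)
    }
  }
})

test_that("attenuation bounds: masked dose never exceeds free dose", {
  sc <- random_scene("mask", seed = 21)
  rf <- toy_rf(seed = 21)
  free <- compute_dose_map(rf, cloud = sc$cloud, ground = sc$ground)
  att <- compute_dose_map(rf, cloud = sc$cloud, ground = sc$ground,
                          mask = sc$mask)
  keep <- !att$skipped
  expect_true(all(att$values[keep] <= free$values[keep] * (1 + 1e-12)))
  # with mu -> infinity every blocked ray vanishes; fully-enclosing mask
  # drives the dose of an interior shielded target to ~0
  dense <- obstacle_mask(sc$spec, sc$mask$occupied, mu = 1e6)
  hard <- compute_dose_map(rf, cloud = sc$cloud, ground = sc$ground,
                           mask = dense)
  expect_true(all(hard$values[keep] <= att$values[keep] * (1 + 1e-12)))
})

test_that("elevated targets shift the response index (cloud shine only)", {
  rf <- toy_rf()
  spec <- grid_spec(0, 0, 1, 15, 15, z_edges = c(0, 2, 4, 6, 8, 10))
  set.seed(9)
  cloud <- concentration_field(spec, array(runif(15 * 15 * 5), c(15, 15, 5)))
  flat <- elevation_map(spec, matrix(0L, 15, 15), cell_size = 2)
  m0 <- compute_dose_map(rf, cloud = cloud)
  me <- compute_dose_map(rf, cloud = cloud, elevation = flat)
  expect_identical(m0$values, me$values)        # h = 0 reduces to Eq-1 form
  # single source at layer n0 over an offset-h target: one shifted term
  cl <- array(0, c(15, 15, 5)); cl[8, 8, 4] <- 2
  c1 <- concentration_field(spec, cl)
  off <- matrix(0L, 15, 15); off[8, 8] <- 2L
  elev <- elevation_map(spec, off, cell_size = 2)
  v <- dose_at_cell_elevated(8, 8, rf, c1, elev)
  zq <- pmin(pmax(layer_centers(spec), 1), 30)
  rfa2 <- altitude_interpolate(rf, zq[2])       # response layer n0 - h = 2
  A <- 2 * 1 * 1 * 2                            # c * dx^2 * thickness
  expect_equal(v, rfa2[rf$half_l + 1, rf$half_l + 1] * A, tolerance = 1e-12)
  # elevation oracle on random scenes
  for (seed in 31:32) {
    sc <- random_scene("elev", seed = seed)
    rfs <- toy_rf(seed = seed)
    m <- compute_dose_map(rfs, cloud = sc$cloud, elevation = sc$elev)
    set.seed(seed)
    for (q in 1:6) {
      i <- sample(21, 1); j <- sample(21, 1)
      o <- oracle_dose_cell(i, j, rfs, sc$cloud, elevation = sc$elev)
      expect_equal(m$values[i, j], o, tolerance = 1e-12)
    }
  }
  # offsets >= layer count are degenerate
  bad <- matrix(0L, 15, 15); bad[2, 2] <- 5L
  expect_error(compute_dose_map(rf, cloud = cloud,
                                elevation = elevation_map(spec, bad, 2)),
               class = "shinemap_degenerate_elevation")
})

test_that("elevated cells under an overhead plume gain dose", {
  # physical response function: raising the target toward the plume must
  # increase cloud shine (altitude monotonicity near the origin)
  rf <- small_rf_137cs()
  spec <- grid_spec(0, 0, 1, 9, 9, z_edges = c(0, 4, 8, 12, 16, 20, 24, 28))
  vals <- array(0, c(9, 9, 7)); vals[, , 6] <- 1   # plume layer at 22 m
  cloud <- concentration_field(spec, vals)
  m0 <- compute_dose_map(rf, cloud = cloud)
  off <- matrix(0L, 9, 9); off[5, 5] <- 2L
  me <- compute_dose_map(rf, cloud = cloud,
                         elevation = elevation_map(spec, off, cell_size = 4))
  expect_gt(me$values[5, 5], m0$values[5, 5])
})

test_that("dose maps are linear and superpose", {
  sc <- random_scene("plain", seed = 41)
  rf <- toy_rf(seed = 41)
  m1 <- compute_dose_map(rf, cloud = sc$cloud, ground = sc$ground)
  m2 <- compute_dose_map(
    rf,
    cloud = concentration_field(sc$spec, 2 * sc$cloud$values),
    ground = surface_deposition(sc$spec, 2 * sc$ground$values))
  expect_equal(m2$values, 2 * m1$values, tolerance = 1e-15)
  sc2 <- random_scene("plain", seed = 42)
  mb <- compute_dose_map(rf, cloud = sc2$cloud, ground = sc2$ground)
  msum <- compute_dose_map(
    rf,
    cloud = concentration_field(sc$spec, sc$cloud$values + sc2$cloud$values),
    ground = surface_deposition(sc$spec, sc$ground$values + sc2$ground$values))
  expect_equal(msum$values, m1$values + mb$values, tolerance = 1e-12)
})

test_that("obstacle targets are skipped and zero sources change nothing", {
  sc <- random_scene("mask", seed = 51)
  rf <- toy_rf(seed = 51)
  m <- compute_dose_map(rf, cloud = sc$cloud, ground = sc$ground,
                        mask = sc$mask)
  expect_true(all(m$skipped[8:10, 8:10]))       # obstacle column
  expect_true(all(is.finite(m$values[!m$skipped])))
  # adding explicit zero-activity cells leaves the map bitwise unchanged
  cl2 <- sc$cloud$values; cl2[cl2 < 0.6] <- 0
  ma <- compute_dose_map(rf, cloud = concentration_field(sc$spec, cl2),
                         ground = sc$ground, mask = sc$mask)
  expect_true(all(ma$values[!ma$skipped] <= m$values[!m$skipped] + 1e-15))
  # resolution mismatch is a configuration error
  rf2 <- toy_rf(); rf2$resolution <- 2
  expect_error(compute_dose_map(rf2, cloud = sc$cloud),
               class = "shinemap_config_error")
  expect_error(compute_dose_map(rf, cloud = sc$cloud,
                                target = c(5, 4, 1, 21)),
               class = "shinemap_config_error")
})

test_that("enlarging the lattice support never decreases doses", {
  rf_small <- build_cloud_response("137Cs", altitudes = 30, half_extent = 6L)
  rf_big <- build_cloud_response("137Cs", altitudes = 30, half_extent = 14L)
  spec <- grid_spec(0, 0, 1, 29, 29, z_edges = c(0, 60))
  cloud <- concentration_field(spec, array(1, c(29, 29, 1)))
  ms <- compute_dose_map(rf_small, cloud = cloud)
  mb <- compute_dose_map(rf_big, cloud = cloud)
  expect_true(all(mb$values >= ms$values - 1e-18))
  expect_gt(max(mb$values - ms$values), 0)
})
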