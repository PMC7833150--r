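test_that("ground response: noble gases refused, symmetry holds", {
  expect_error(build_ground_response("85Kr"), class = "shinemap_no_ground_source")
  expect_error(build_ground_response("133Xe"), class = "shinemap_no_ground_source")
  rf <- small_rf_137cs()
  g <- rf$ground
  expect_true(all(abs(g - g[rev(seq_len(nrow(g))), rev(seq_len(ncol(g)))]) <
                  1e-12 * max(g)))          # R(l,m,0) = R(-l,-m,0)
  expect_true(all(is.finite(g)) && all(g >= 0))
})

test_that("origin ground cell matches a brute-force patch quadrature", {
  # single 661.66 keV line, attenuation and buildup disabled: the origin
  # value is the integral of K * I * coeff / (u^2 + v^2 + 1) over the patch
  rf <- build_ground_response("137Cs", half_extent = 1L,
                              attenuation = FALSE, use_buildup = FALSE,
                              ground_correction = FALSE, soil_blocking = FALSE)
  coeff <- fluence_to_dose("H*(10)", 661.66)
  K <- 3.6e-3 / (4 * pi * 1e4)
  n <- 400L
  u <- (seq_len(n) - 0.5) / n - 0.5
  U <- matrix(u, n, n); V <- t(U)
  oracle <- mean(K * 0.851 * coeff / (U^2 + V^2 + 1))
  expect_equal(rf$ground[2L, 2L], oracle, tolerance = 1e-5)
})

test_that("cloud response has lattice symmetry and a vacuum-limit check", {
  rf <- small_rf_137cs()
  for (n in seq_along(rf$altitudes)) {
    lay <- rf$cloud[, , n]
    expect_equal(lay, lay[rev(seq_len(nrow(lay))), ], tolerance = 1e-12)
    expect_equal(lay, lay[, rev(seq_len(ncol(lay)))], tolerance = 1e-12)
  }
  # inverse-square closed form when all transport corrections are off
  rfv <- build_cloud_response("137Cs", altitudes = 100, half_extent = 25L,
                              attenuation = FALSE, use_buildup = FALSE,
                              ground_correction = FALSE, soil_blocking = FALSE)
  coeff <- fluence_to_dose("H*(10)", 661.66)
  K <- 3.6e-3 / (4 * pi * 1e4)
  for (d in c(5L, 12L, 25L)) {
    r2 <- d^2 + 99^2
    expect_equal(rfv$cloud[26L + d, 26L, 1L], K * 0.851 * coeff / r2,
                 tolerance = 1e-6)
  }
})

test_that("responses decay monotonically with distance and altitude", {
  rf <- small_rf_137cs()
  c0 <- rf$half_l + 1L
  ray <- rf$ground[c0:(2L * rf$half_l + 1L), c0]
  expect_true(all(diff(ray) < 0))
  for (n in seq_along(rf$altitudes))
    expect_true(all(diff(rf$cloud[c0:(2L * rf$half_l + 1L), c0, n]) < 0))
  expect_true(all(diff(rf$cloud[c0, c0, ]) < 0))  # R(0,0,.) falls with altitude
})

test_that("doubling air attenuation never increases any lattice value", {
  a1 <- build_cloud_response("137Cs", altitudes = c(10, 100),
                             half_extent = 40L)
  a2 <- build_cloud_response("137Cs", altitudes = c(10, 100),
                             half_extent = 40L, air_density = 2 * 1.205e-3)
  expect_true(all(a2$cloud <= a1$cloud * (1 + 1e-12)))
})

test_that("horizontal resize implements centred block means with truncation", {
  rf <- small_rf_137cs()
  expect_identical(resize_horizontal(rf, 1), rf)        # k = 1 identity
  const <- shinemap:::.rf_new("137Cs", "hstar10", 1, 4L, 4L,
                              ground = matrix(3.5, 9, 9))
  rc <- resize_horizontal(const, 3)
  expect_true(all(rc$ground == 3.5))                    # mean of equal values
  expect_identical(rc$half_l, 1L)                       # (2*1+1)*3 = 9
  # 5x5 toy lattice, k = 3: single output = mean of the central 3x3 block
  toy <- shinemap:::.rf_new("137Cs", "hstar10", 1, 2L, 2L,
                            ground = matrix(as.numeric(1:25), 5, 5))
  r1 <- resize_horizontal(toy, 3)
  expect_identical(dim(r1$ground), c(1L, 1L))
  expect_equal(r1$ground[1L, 1L], mean(matrix(1:25, 5, 5)[2:4, 2:4]))
  expect_error(resize_horizontal(rf, 2.5), class = "shinemap_resolution_error")
  expect_error(resize_horizontal(resize_horizontal(rf, 3), 1),
               class = "shinemap_resolution_error")     # ratio < 1
  # native 1001-cell convention: k = 5 keeps 199 cells (truncated remainder)
  expect_identical(((2L * 500L + 1L) %/% 5L - 1L) %/% 2L, 99L)
})

test_that("altitude interpolation is exact at nodes and log-log in between", {
  rf <- small_rf_137cs()
  expect_identical(altitude_interpolate(rf, 10), rf$cloud[, , 3L])
  # two-node geometric-mean identity
  two <- shinemap:::.rf_new("137Cs", "hstar10", 1, 1L, 1L,
                            cloud = array(rep(c(4, 1), each = 9), c(3, 3, 2)),
                            altitudes = c(10, 1000))
  expect_equal(altitude_interpolate(two, 100), matrix(2, 3, 3))
  # scalar log-log oracle, arbitrary altitude between 20 and 30 m
  z <- 23.7
  lay <- altitude_interpolate(rf, z)
  t <- (log(z) - log(20)) / (log(30) - log(20))
  sc <- exp((1 - t) * log(rf$cloud[5L, 9L, 4L]) + t * log(rf$cloud[5L, 9L, 5L]))
  expect_equal(lay[5L, 9L], sc, tolerance = 1e-14)
  # zero node values propagate as zero
  zrf <- shinemap:::.rf_new("137Cs", "hstar10", 1, 0L, 0L,
                            cloud = array(c(0, 5), c(1, 1, 2)),
                            altitudes = c(10, 1000))
  expect_identical(altitude_interpolate(zrf, 100)[1L], 0)
  expect_error(altitude_interpolate(rf, 0.5),
               class = "shinemap_altitude_range_error")
  expect_error(altitude_interpolate(rf, 2000),
               class = "shinemap_altitude_range_error")
})

test_that("reciprocity: swapping source and receptor leaves the kernel fixed", {
  k1 <- shinemap:::.point_kernel(300, 0, 80, 1, 0.851, 3.7, 9.28e-3,
                                 1.1, 0.07, 12.9)
  k2 <- shinemap:::.point_kernel(-300, 0, 1, 80, 0.851, 3.7, 9.28e-3,
                                 1.1, 0.07, 12.9)
  expect_identical(k1, k2)
})

test_that("binary archive round trip is bit-exact and validated", {
  rf <- small_rf_137cs()
  f <- tempfile(fileext = ".rf")
  save_rf(rf, f)
  rt <- load_rf(f)
  expect_identical(rt$ground, rf$ground)
  expect_identical(rt$cloud, rf$cloud)
  expect_identical(rt$altitudes, as.numeric(rf$altitudes))
  expect_identical(rt$nuclide, rf$nuclide)
  expect_identical(rt$quantity, rf$quantity)
  # truncation by 8 bytes
  sz <- file.size(f)
  raw <- readBin(f, "raw", sz)
  f2 <- tempfile(fileext = ".rf")
  writeBin(raw[seq_len(sz - 8L)], f2)
  expect_error(load_rf(f2), class = "shinemap_format_error")
  # bad magic
  raw3 <- raw; raw3[1:4] <- charToRaw("XXXX")
  f3 <- tempfile(fileext = ".rf")
  writeBin(raw3, f3)
  expect_error(load_rf(f3), class = "shinemap_format_error")
  # unknown quantity code (byte offset: 4 magic + 4 version + 16 nuclide)
  raw4 <- raw; raw4[25L] <- as.raw(99L)
  f4 <- tempfile(fileext = ".rf")
  writeBin(raw4, f4)
  expect_error(load_rf(f4), class = "shinemap_format_error")
  # manifest lists the archive
  dir <- tempfile(); dir.create(dir)
  save_rf(rf, file.path(dir, "cs137.rf"))
  mf <- save_rf_manifest(dir)
  y <- yaml::read_yaml(mf)
  expect_identical(y$archives[[1L]]$nuclide, "137Cs")
})
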