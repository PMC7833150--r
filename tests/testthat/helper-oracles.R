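# Shared fixtures and independent oracles.  The oracles deliberately take a
# different computational route from the package kernels: naive index loops
# for the lattice sum, axis-aligned box-intersection intervals for ray
# chords, fine midpoint grids for quadrature.

.memo <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (is.null(.memo[[key]])) .memo[[key]] <- force(expr)
  .memo[[key]]
}

# A toy response function with explicit values (no physics), resolution 1 m.
toy_rf <- function(L = 6L, n_alt = 5L, seed = 1L,
                   altitudes = c(1, 5, 10, 20, 30)[seq_len(n_alt)]) {
  set.seed(seed)
  nl <- 2L * L + 1L
  shinemap:::.rf_new("137Cs", "hstar10", 1, L, L,
                     ground = matrix(runif(nl * nl, 0.1, 1), nl, nl),
                     cloud = array(runif(nl * nl * n_alt, 0.1, 1),
                                   c(nl, nl, n_alt)),
                     altitudes = altitudes)
}

# Naive lattice-sum oracle for one target cell: explicit loops over source
# layer n (0 = ground), m and l, with optional chord attenuation and
# elevation index shift.  Activities are converted exactly as the engine
# documents: density times cell area/volume.
oracle_dose_cell <- function(i, j, rf, cloud = NULL, ground = NULL,
                             mask = NULL, elevation = NULL) {
  spec <- if (!is.null(cloud)) cloud$spec else ground$spec
  L <- rf$half_l
  th <- layer_thickness(spec)
  zc <- layer_centers(spec)
  K <- length(zc)
  h <- if (is.null(elevation)) 0L else elevation$offsets[i, j]
  vs <- if (is.null(elevation)) 0 else elevation$cell_size
  zt <- 1 + h * vs
  xt <- spec$x_min + (i - 0.5) * spec$dx
  yt <- spec$y_min + (j - 0.5) * spec$dx
  if (!is.null(mask)) {
    kt <- findInterval(zt, spec$z_edges, rightmost.closed = FALSE)
    if (kt >= 1 && kt <= K && mask$occupied[i, j, kt]) return(NA_real_)
  }
  rfa <- NULL
  if (!is.null(rf$cloud)) {
    zq <- pmin(pmax(zc, min(rf$altitudes)), max(rf$altitudes))
    rfa <- array(0, c(2L * L + 1L, 2L * L + 1L, K))
    for (n in seq_len(K)) rfa[, , n] <- altitude_interpolate(rf, zq[n])
  }
  att <- function(xs, ys, zs) {
    if (is.null(mask) || mask$mu <= 0) return(1)
    exp(-mask$mu * oracle_chord(c(xs, ys, zs), c(xt, yt, zt), mask))
  }
  tot <- 0
  if (!is.null(ground) && !is.null(rf$ground) && h == 0L) {
    for (m in -L:L) for (l in -L:L) {
      is <- i + l; js <- j + m
      if (is < 1 || is > spec$nx || js < 1 || js > spec$ny) next
      A <- ground$values[is, js] * spec$dx^2
      if (A <= 0) next
      xs <- spec$x_min + (is - 0.5) * spec$dx
      ys <- spec$y_min + (js - 0.5) * spec$dx
      tot <- tot + rf$ground[l + L + 1L, m + L + 1L] * A * att(xs, ys, 1e-6)
    }
  }
  if (!is.null(cloud) && !is.null(rfa)) {
    for (n in seq_len(K)) {
      if (n <= h) next
      for (m in -L:L) for (l in -L:L) {
        is <- i + l; js <- j + m
        if (is < 1 || is > spec$nx || js < 1 || js > spec$ny) next
        A <- cloud$values[is, js, n] * spec$dx^2 * th[n]
        if (A <= 0) next
        xs <- spec$x_min + (is - 0.5) * spec$dx
        ys <- spec$y_min + (js - 0.5) * spec$dx
        tot <- tot + rfa[l + L + 1L, m + L + 1L, n - h] * A *
          att(xs, ys, zc[n])
      }
    }
  }
  tot
}

# Chord oracle: sum of segment-AABB intersection lengths over the list of
# occupied voxels (independent of the traversal used by the engine).
oracle_chord <- function(src, tgt, mask) {
  spec <- mask$spec
  occ <- which(mask$occupied, arr.ind = TRUE)
  if (nrow(occ) == 0L) return(0)
  d <- tgt - src
  len <- sqrt(sum(d^2))
  lo_x <- spec$x_min + (occ[, 1L] - 1L) * spec$dx
  lo_y <- spec$y_min + (occ[, 2L] - 1L) * spec$dx
  lo_z <- spec$z_edges[occ[, 3L]]
  hi_x <- lo_x + spec$dx
  hi_y <- lo_y + spec$dx
  hi_z <- spec$z_edges[occ[, 3L] + 1L]
  t0 <- rep(0, nrow(occ)); t1 <- rep(1, nrow(occ))
  clip <- function(p, dd, lo, hi) {
    if (abs(dd) < 1e-300) {
      keep <- p >= lo & p <= hi
      t0 <<- ifelse(keep, t0, 1); t1 <<- ifelse(keep, t1, 0)
    } else {
      ta <- (lo - p) / dd; tb <- (hi - p) / dd
      t0 <<- pmax(t0, pmin(ta, tb)); t1 <<- pmin(t1, pmax(ta, tb))
    }
  }
  clip(src[1L], d[1L], lo_x, hi_x)
  clip(src[2L], d[2L], lo_y, hi_y)
  clip(src[3L], d[3L], lo_z, hi_z)
  sum(pmax(t1 - t0, 0)) * len
}

# Random sparse scene on a 21 x 21 x 5 grid; kinds: "plain", "mask", "elev".
random_scene <- function(kind = "plain", seed = 1L) {
  set.seed(seed)
  spec <- grid_spec(0, 0, 1, 21, 21, z_edges = c(0, 2, 4, 6, 8, 10))
  cl <- array(0, c(21, 21, 5))
  n_src <- if (kind == "mask") 15L else 60L
  idx <- cbind(sample(21, n_src, TRUE), sample(21, n_src, TRUE),
               sample(5, n_src, TRUE))
  cl[idx] <- runif(n_src, 0.5, 2)
  gd <- matrix(0, 21, 21)
  gidx <- cbind(sample(21, 20L, TRUE), sample(21, 20L, TRUE))
  gd[gidx] <- runif(20L, 0.5, 2)
  mask <- NULL; elev <- NULL
  if (kind == "mask") {
    occ <- array(FALSE, c(21, 21, 5))
    occ[8:10, 8:10, 1:2] <- TRUE
    occ[15:16, 4:5, 1:3] <- TRUE
    mask <- obstacle_mask(spec, occ, mu = 1.85)
  }
  if (kind == "elev") {
    off <- matrix(0L, 21, 21)
    off[14:21, ] <- 1L
    off[18:21, ] <- 3L
    elev <- elevation_map(spec, off, cell_size = 2)
  }
  list(spec = spec,
       cloud = concentration_field(spec, cl),
       ground = surface_deposition(spec, gd),
       mask = mask, elev = elev)
}

# Crosswind-plane mass flux of a Gaussian plume at downwind distance x,
# by midpoint quadrature over y and z (should recover Q).
plume_flux <- function(pp, x, n = 1200L) {
  s <- sigma_yz(x, pp$stability_class)
  wy <- 12 * s$sigma_y
  zt <- pp$H + 12 * s$sigma_z
  dy <- 2 * wy / n
  dz <- zt / n
  y <- -wy + (seq_len(n) - 0.5) * dy
  z <- (seq_len(n) - 0.5) * dz
  C <- outer(y, z, function(yy, zz) concentration_at(pp, x, yy, zz))
  sum(C) * dy * dz * pp$U
}

small_rf_137cs <- function() {
  memoize("small_rf_137cs", {
    cl <- build_cloud_response("137Cs", "H*(10)",
                               altitudes = c(1, 5, 10, 20, 30),
                               half_extent = 10L)
    gr <- build_ground_response("137Cs", "H*(10)", half_extent = 10L)
    rf_combine(gr, cl)
  })
}

building_fixture <- function() {
  memoize("building_fixture", make_building_array(seed = 7L, resolution = 4))
}

building_rf4 <- function() {
  memoize("building_rf4", {
    rf <- build_response_function(
      "137Cs", "H*(10)",
      altitudes = altitude_nodes()[altitude_nodes() <= 200])
    resize_horizontal(rf, 4)
  })
}
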