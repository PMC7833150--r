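## Lattice dose-response functions: dose rate at a ground-level receptor
## (1 m above grade) per unit activity in a source cell, indexed by
## horizontal offset (l, m) and source layer n (0 = areal ground source,
## n >= 1 = cloud layers at fixed altitude nodes).
##
## The lattice is built with a point-kernel model: uncollided inverse-square
## transport with exponential air attenuation, a Berger buildup factor for
## in-air scatter, and a ground-truncation factor that removes the part of
## the scatter volume lying below grade (this is what makes low-altitude
## distant sources fall below higher ones, as the blocked-by-soil argument
## predicts).  Rays with an endpoint below grade are additionally attenuated
## along the sub-surface soil chord.

#' Altitude nodes of the cloud response lattice
#'
#' The fixed altitudes (m) at which cloud-source layers are evaluated;
#' intermediate altitudes are obtained by \code{\link{altitude_interpolate}}.
#' @return Numeric vector of 17 altitudes from 1 to 1000 m.
#' @export
altitude_nodes <- function() {
  c(1, 5, 10, 20, 30, 40, 50, 60, 80, 100, 125, 150, 200, 350, 500, 750, 1000)
}

## 6-point Gauss-Legendre nodes/weights on [-1/2, 1/2] (no node at the
## centre, so a receptor inside a source voxel never sees r = 0).
.gl6 <- list(
  x = c(-0.4662347571015760, -0.3306046932331323, -0.1193095930415985,
         0.1193095930415985,  0.3306046932331323,  0.4662347571015760),
  w = c(0.0856622461895852, 0.1803807865240693, 0.2339569672863455,
        0.2339569672863455, 0.1803807865240693, 0.0856622461895852))

.kernel_constant <- 3.6e-3 / (4 * pi * 1e4)  # kBq, pSv cm2, r in m -> mSv/h

## Point-kernel evaluation, vectorised over source positions.
## dx, dy: horizontal offsets source -> receptor (m); zs, zr: heights (m).
## Returns dose rate (mSv/h) per 1 kBq point source per unit conversion
## coefficient and line intensity already folded in by the caller? No:
## intensity and coeff are arguments so callers stay declarative.
.point_kernel <- function(dx, dy, zs, zr, intensity, coeff, mu_air,
                          berger_a, berger_b, mu_soil,
                          attenuation = TRUE, use_buildup = TRUE,
                          ground_correction = TRUE, soil_blocking = TRUE) {
  r2 <- dx * dx + dy * dy + (zs - zr)^2
  r <- sqrt(r2)
  r2 <- pmax(r2, 1e-12)
  out <- .kernel_constant * intensity * coeff / r2
  if (attenuation || use_buildup) mur <- mu_air * r
  if (attenuation) out <- out * exp(-mur)
  if (use_buildup) {
    w <- 1
    if (ground_correction && mu_air > 0) {
      lambda <- 1 / mu_air
      t <- pmin(pmax((zs + zr) / 2, 0) / lambda, 1)
      w <- 0.5 + 0.75 * t - 0.25 * t^3   # scatter-sphere fraction above grade
    }
    out <- out * (1 + berger_a * mur * exp(berger_b * mur) * w)
  }
  if (soil_blocking) {
    below <- pmin(zs, zr) < 0
    if (any(below)) {
      frac <- abs(pmin(zs, zr))[below] / pmax(abs(zs - zr)[below], 1e-12)
      out[below] <- out[below] * exp(-mu_soil * frac * r[below])
    }
  }
  out
}

.rf_new <- function(nuclide, quantity, resolution, half_l, half_m,
                    ground = NULL, cloud = NULL, altitudes = numeric(0)) {
  structure(list(nuclide = nuclide, quantity = quantity,
                 resolution = resolution, half_l = half_l, half_m = half_m,
                 ground = ground, cloud = cloud, altitudes = altitudes),
            class = "dose_response_function")
}

#' @export
print.dose_response_function <- function(x, ...) {
  cat("<dose_response_function>", x$nuclide, x$quantity, "\n",
      sprintf(" resolution %g m, half extents (%d, %d) cells\n",
              x$resolution, x$half_l, x$half_m),
      if (!is.null(x$ground)) " ground layer present\n" else " no ground layer\n",
      sprintf(" %d cloud layers at altitudes: %s m\n", length(x$altitudes),
              paste(x$altitudes, collapse = ", ")))
  invisible(x)
}

## Build one lattice layer for all gamma lines of a nuclide.
## zs: source height (m); receptor fixed at (0, 0, 1).  Near-field cells
## (centre distance < 10 m) are integrated with 6-point Gauss-Legendre
## quadrature per dimension over the source patch (2-D for the areal ground
## source, 3-D for a 1 m cloud voxel); farther cells use a midpoint
## evaluation.
.build_layer <- function(lines, quantity, zs, half_l, half_m, resolution,
                         volumetric, air_density, options) {
  nl <- 2L * half_l + 1L
  nm <- 2L * half_m + 1L
  lx <- (-half_l:half_l) * resolution
  my <- (-half_m:half_m) * resolution
  DX <- matrix(lx, nl, nm)
  DY <- matrix(my, nl, nm, byrow = TRUE)
  zr <- 1
  out <- matrix(0, nl, nm)
  near <- sqrt(DX^2 + DY^2 + (zs - zr)^2) < 10
  g <- .gl6
  for (k in seq_len(nrow(lines))) {
    E <- lines$energy_keV[k]
    I <- lines$intensity[k]
    coeff <- fluence_to_dose(quantity, E)
    mu_air <- linear_attenuation("air", E, air_density)
    mu_soil <- linear_attenuation("soil", E)
    ab <- .berger_ab("air", E)
    args <- c(list(intensity = I, coeff = coeff, mu_air = mu_air,
                   berger_a = ab$a, berger_b = ab$b, mu_soil = mu_soil),
              options)
    val <- do.call(.point_kernel,
                   c(list(dx = DX, dy = DY, zs = zs, zr = zr), args))
    if (any(near)) {
      acc <- matrix(0, sum(near), 1)
      dxn <- DX[near]; dyn <- DY[near]
      if (volumetric) {
        for (ix in 1:6) for (iy in 1:6) for (iz in 1:6) {
          w <- g$w[ix] * g$w[iy] * g$w[iz]
          acc <- acc + w * do.call(.point_kernel, c(list(
            dx = dxn + g$x[ix] * resolution, dy = dyn + g$x[iy] * resolution,
            zs = zs + g$x[iz], zr = zr), args))
        }
      } else {
        for (ix in 1:6) for (iy in 1:6) {
          w <- g$w[ix] * g$w[iy]
          acc <- acc + w * do.call(.point_kernel, c(list(
            dx = dxn + g$x[ix] * resolution, dy = dyn + g$x[iy] * resolution,
            zs = zs, zr = zr), args))
        }
      }
      val[near] <- acc
    }
    out <- out + val
  }
  out
}

#' Build the ground (areal-source) response layer
#'
#' Dose rate at a receptor 1 m above grade per 1 kBq distributed uniformly
#' over a source patch on the ground (z = 0), for every horizontal offset of
#' the lattice.  Noble gases carry no ground source.
#'
#' @param nuclide Nuclide identifier.
#' @param quantity \code{"H*(10)"} (mSv/h) or \code{"air kerma"} (mGy/h).
#' @param half_extent Half extent of the lattice in cells (default 500,
#'   i.e. the native 1001 x 1001 domain at 1 m resolution).
#' @param resolution Cell size in m (native builds use 1 m).
#' @param air_density Air density in g/cm3.
#' @param attenuation,use_buildup,ground_correction,soil_blocking Model
#'   switches, mainly for validation against closed-form limits.
#' @return A \code{dose_response_function} with only the ground layer.
#' @export
build_ground_response <- function(nuclide, quantity = "H*(10)",
                                  half_extent = 500L, resolution = 1,
                                  air_density = 1.205e-3,
                                  attenuation = TRUE, use_buildup = TRUE,
                                  ground_correction = TRUE,
                                  soil_blocking = TRUE) {
  info <- nuclide_info(nuclide)
  if (info$is_noble_gas)
    .stop_cls("shinemap_no_ground_source",
              "no ground-source response for noble gas ", nuclide)
  opts <- list(attenuation = attenuation, use_buildup = use_buildup,
               ground_correction = ground_correction,
               soil_blocking = soil_blocking)
  q <- .normalize_quantity(quantity)
  ground <- .build_layer(info$lines, q, zs = 0, half_extent, half_extent,
                         resolution, volumetric = FALSE, air_density, opts)
  .rf_new(nuclide, q, resolution, half_extent, half_extent, ground = ground)
}

#' Build the cloud (volume-source) response layers
#'
#' One lattice layer per altitude node: dose rate at the ground-level
#' receptor per 1 kBq in a source voxel at that altitude.  By transport
#' reciprocity the kernel is symmetric in source and receptor, so evaluating
#' source-over-receptor covers every source position at once.
#'
#' @inheritParams build_ground_response
#' @param altitudes Altitude nodes (m); default the 17 packaged nodes.
#' @return A \code{dose_response_function} with cloud layers only.
#' @export
build_cloud_response <- function(nuclide, quantity = "H*(10)",
                                 altitudes = altitude_nodes(),
                                 half_extent = 500L, resolution = 1,
                                 air_density = 1.205e-3,
                                 attenuation = TRUE, use_buildup = TRUE,
                                 ground_correction = TRUE,
                                 soil_blocking = TRUE) {
  info <- nuclide_info(nuclide)
  stopifnot(all(altitudes >= 1), all(altitudes <= 1000),
            !is.unsorted(altitudes, strictly = TRUE))
  opts <- list(attenuation = attenuation, use_buildup = use_buildup,
               ground_correction = ground_correction,
               soil_blocking = soil_blocking)
  q <- .normalize_quantity(quantity)
  nl <- 2L * half_extent + 1L
  cloud <- array(0, c(nl, nl, length(altitudes)))
  for (n in seq_along(altitudes)) {
    cloud[, , n] <- .build_layer(info$lines, q, zs = altitudes[n],
                                 half_extent, half_extent, resolution,
                                 volumetric = TRUE, air_density, opts)
  }
  .rf_new(nuclide, q, resolution, half_extent, half_extent,
          cloud = cloud, altitudes = altitudes)
}

#' Build ground and cloud response lattices together
#'
#' Convenience wrapper building the full response function (ground layer is
#' omitted, with a flag, for noble gases).
#' @inheritParams build_cloud_response
#' @export
build_response_function <- function(nuclide, quantity = "H*(10)",
                                    altitudes = altitude_nodes(),
                                    half_extent = 500L, resolution = 1, ...) {
  cl <- build_cloud_response(nuclide, quantity, altitudes, half_extent,
                             resolution, ...)
  if (nuclide_info(nuclide)$is_noble_gas) return(cl)
  gr <- build_ground_response(nuclide, quantity, half_extent, resolution, ...)
  rf_combine(gr, cl)
}

#' Combine ground-only and cloud-only response functions
#' @param ground_rf,cloud_rf \code{dose_response_function}s for the same
#'   nuclide, quantity and geometry.
#' @export
rf_combine <- function(ground_rf, cloud_rf) {
  stopifnot(identical(ground_rf$nuclide, cloud_rf$nuclide),
            identical(ground_rf$quantity, cloud_rf$quantity),
            ground_rf$resolution == cloud_rf$resolution,
            ground_rf$half_l == cloud_rf$half_l)
  .rf_new(ground_rf$nuclide, ground_rf$quantity, ground_rf$resolution,
          ground_rf$half_l, ground_rf$half_m,
          ground = ground_rf$ground, cloud = cloud_rf$cloud,
          altitudes = cloud_rf$altitudes)
}

.block_mean <- function(mat, k, half_out) {
  nb <- 2L * half_out + 1L
  c0 <- (nrow(mat) + 1L) %/% 2L          # origin index
  lo <- c0 - half_out * k - (k - 1L) %/% 2L
  sub <- mat[lo:(lo + nb * k - 1L), lo:(lo + nb * k - 1L)]
  s1 <- colSums(array(sub, c(k, nb * k * nb)))          # reduce rows
  b <- array(s1, c(nb, k, nb))
  s2 <- colSums(array(aperm(b, c(2L, 1L, 3L)), c(k, nb * nb)))
  matrix(s2, nb, nb) / (k * k)
}

#' Resize a response function to a coarser horizontal resolution
#'
#' Each output value is the arithmetic mean of its k x k source block
#' (k = target/native ratio), blocks centred on the origin cell; the lattice
#' is truncated to the largest odd extent that fits, discarding division
#' remainders.  The resized value is therefore the dose per unit *total*
#' activity (kBq) placed uniformly in the coarse cell.
#'
#' @param rf A \code{dose_response_function}.
#' @param target_resolution Target cell size (m); must be an integer
#'   multiple of the native resolution.
#' @export
resize_horizontal <- function(rf, target_resolution) {
  ratio <- target_resolution / rf$resolution
  if (ratio < 1 || abs(ratio - round(ratio)) > 1e-9)
    .stop_cls("shinemap_resolution_error",
              "target resolution must be an integer multiple (>= 1) of ",
              rf$resolution, " m")
  k <- as.integer(round(ratio))
  if (k == 1L) return(rf)
  n_native <- 2L * rf$half_l + 1L
  half_out <- ((n_native %/% k) - 1L) %/% 2L
  if (half_out < 0L)
    .stop_cls("shinemap_resolution_error", "lattice too small for ratio ", k)
  ground <- if (!is.null(rf$ground)) .block_mean(rf$ground, k, half_out)
  cloud <- NULL
  if (!is.null(rf$cloud)) {
    nb <- 2L * half_out + 1L
    cloud <- array(0, c(nb, nb, dim(rf$cloud)[3L]))
    for (n in seq_len(dim(rf$cloud)[3L]))
      cloud[, , n] <- .block_mean(rf$cloud[, , n], k, half_out)
  }
  .rf_new(rf$nuclide, rf$quantity, target_resolution, half_out, half_out,
          ground = ground, cloud = cloud, altitudes = rf$altitudes)
}

#' Interpolate cloud layers to an arbitrary altitude
#'
#' Elementwise logarithmic interpolation between bracketing altitude nodes:
#' linear in (ln z, ln R).  At a node the stored layer is returned exactly;
#' a zero value at either bracketing node propagates as zero.
#'
#' @param rf A \code{dose_response_function} with cloud layers.
#' @param z Altitude in m, within [min node, max node].
#' @return Matrix lattice layer.
#' @export
altitude_interpolate <- function(rf, z) {
  if (is.null(rf$cloud)) .stop_cls("shinemap_altitude_range_error",
                                   "response function has no cloud layers")
  nodes <- rf$altitudes
  if (z < nodes[1L] || z > nodes[length(nodes)])
    .stop_cls("shinemap_altitude_range_error",
              "altitude ", z, " m outside node range [", nodes[1L], ", ",
              nodes[length(nodes)], "]")
  i <- findInterval(z, nodes)
  if (z == nodes[i]) return(rf$cloud[, , i])
  r1 <- rf$cloud[, , i]
  r2 <- rf$cloud[, , i + 1L]
  t <- (log(z) - log(nodes[i])) / (log(nodes[i + 1L]) - log(nodes[i]))
  out <- exp((1 - t) * log(r1) + t * log(r2))
  out[r1 <= 0 | r2 <= 0] <- 0
  out
}
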