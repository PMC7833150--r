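## R-side driver for the lattice dose convolution.
##
## A "job" bundles everything the kernel needs: the response function
## resized to the field resolution and vertically aligned to the field's
## layer-centre altitudes, per-cell activities (kBq), the obstacle mask,
## elevation offsets and the target window.  compute_dose_map() is the
## one-shot entry point; run_parallel() executes the same job tilewise.

.align_rf_layers <- function(rf, spec) {
  zc <- layer_centers(spec)
  if (is.null(rf$cloud)) return(NULL)
  ## clamp sub-metre layer centres to the lowest altitude node; the lattice
  ## is not defined below 1 m
  zc <- pmin(pmax(zc, min(rf$altitudes)), max(rf$altitudes))
  nl <- 2L * rf$half_l + 1L
  out <- array(0, c(nl, nl, length(zc)))
  for (n in seq_along(zc)) out[, , n] <- altitude_interpolate(rf, zc[n])
  out
}

#' Assemble a dose-calculation job
#'
#' Validates resolutions, converts concentration/deposition densities into
#' per-cell activities (kBq), aligns the response-function layers to the
#' field's layer centres, and freezes the target window.
#'
#' @param rf A \code{dose_response_function} resized to the field
#'   resolution.
#' @param cloud Optional \code{\link{concentration_field}} (kBq/m3).
#' @param ground Optional \code{\link{surface_deposition}} (kBq/m2); wall
#'   faces, if any, must be converted beforehand with
#'   \code{\link{wall_deposition_to_air}} and passed through \code{cloud}.
#' @param mask Optional \code{\link{obstacle_mask}}; enables attenuation
#'   and target skipping.
#' @param elevation Optional \code{\link{elevation_map}}; cloud-shine index
#'   offsets (ground shine is not computed at elevated cells).
#' @param target Optional integer vector \code{c(i0, i1, j0, j1)} (1-based
#'   cell range) delimiting the target window; default the whole grid.
#' @return Object of class \code{shinemap_job}.
#' @export
make_job <- function(rf, cloud = NULL, ground = NULL, mask = NULL,
                     elevation = NULL, target = NULL) {
  if (is.null(cloud) && is.null(ground))
    .stop_cls("shinemap_config_error", "no source fields given")
  spec <- if (!is.null(cloud)) cloud$spec else ground$spec
  if (abs(rf$resolution - spec$dx) > 1e-9)
    .stop_cls("shinemap_config_error",
              "response-function resolution (", rf$resolution,
              " m) does not match field resolution (", spec$dx, " m)")
  for (f in list(cloud, ground, mask, elevation))
    if (!is.null(f) && !.same_spec(f$spec, spec))
      .stop_cls("shinemap_config_error", "field grids are inconsistent")
  if (is.null(target)) target <- c(1L, spec$nx, 1L, spec$ny)
  target <- as.integer(target)
  if (target[1L] > target[2L] || target[3L] > target[4L] ||
      target[1L] < 1L || target[3L] < 1L ||
      target[2L] > spec$nx || target[4L] > spec$ny)
    .stop_cls("shinemap_config_error", "empty or out-of-range target area")
  n_layers <- length(spec$z_edges) - 1L
  cloudA <- numeric(0)
  if (!is.null(cloud)) {
    th <- layer_thickness(spec)
    cloudA <- cloud$values *
      rep(th * spec$dx^2, each = spec$nx * spec$ny)   # kBq per cell
  }
  groundA <- if (!is.null(ground)) ground$values * spec$dx^2 else numeric(0)
  hoff <- if (!is.null(elevation)) elevation$offsets else matrix(0L, 0L, 0L)
  if (!is.null(elevation)) {
    N <- n_layers
    if (max(elevation$offsets) >= N)
      .stop_cls("shinemap_degenerate_elevation",
                "elevation offset >= number of source layers")
  }
  rfc <- .align_rf_layers(rf, spec)
  structure(list(
    spec = spec, rf = rf,
    rfc = if (is.null(rfc)) numeric(0) else rfc,
    rfg = if (is.null(rf$ground)) numeric(0) else rf$ground,
    cloudA = cloudA, groundA = groundA,
    n_layers = n_layers,
    z_centers = layer_centers(spec),
    occ = if (!is.null(mask)) mask$occupied else array(FALSE, c(0L, 0L, 0L)),
    mu = if (!is.null(mask)) mask$mu else 0,
    hoff = hoff,
    vsize = if (!is.null(elevation)) elevation$cell_size else 0,
    target = target,
    nuclide = rf$nuclide, quantity = rf$quantity),
    class = "shinemap_job")
}

.job_cells <- function(job) {
  tw <- job$target[2L] - job$target[1L] + 1L
  th <- job$target[4L] - job$target[3L] + 1L
  seq_len(tw * th) - 1L
}

.job_compute_cells <- function(job, cells) {
  .dose_cells_cpp(
    as.integer(cells),
    job$target[1L] - 1L, job$target[3L] - 1L,
    job$target[2L] - job$target[1L] + 1L,
    job$spec$nx, job$spec$ny,
    job$spec$x_min, job$spec$y_min, job$spec$dx,
    as.numeric(job$groundA), as.numeric(job$cloudA),
    job$n_layers,
    as.numeric(job$rfg), as.numeric(job$rfc),
    job$rf$half_l, job$rf$half_m,
    if (length(job$occ)) as.integer(job$occ) else integer(0),
    as.numeric(job$spec$z_edges),
    job$mu,
    if (length(job$hoff)) as.integer(job$hoff) else integer(0),
    job$vsize,
    as.numeric(job$z_centers))
}

.job_assemble <- function(job, values) {
  tw <- job$target[2L] - job$target[1L] + 1L
  th <- job$target[4L] - job$target[3L] + 1L
  vals <- matrix(values, tw, th)
  structure(list(spec = job$spec, values = vals, skipped = is.na(vals),
                 quantity = job$quantity, nuclide = job$nuclide,
                 window = job$target),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %s %s: %d x %d cells, %d skipped, max %.4g %s\n",
              x$nuclide, x$quantity, nrow(x$values), ncol(x$values),
              sum(x$skipped), max(x$values, na.rm = TRUE),
              if (identical(x$quantity, "kerma")) "mGy/h" else "mSv/h"))
  invisible(x)
}

#' Compute a ground-level dose-rate map
#'
#' Per-cell dispatch of the lattice convolution with obstacle attenuation
#' and terrain-elevation offsets: obstacle-occupied target cells are marked
#' skipped (NA); source cells with zero activity are skipped without
#' changing any value; output is deterministic and independent of traversal
#' order.
#'
#' @inheritParams make_job
#' @return A \code{dose_map}: values matrix (mSv/h or mGy/h) over the
#'   target window with NA at skipped cells, plus the skip mask.
#' @export
compute_dose_map <- function(rf, cloud = NULL, ground = NULL, mask = NULL,
                             elevation = NULL, target = NULL) {
  job <- make_job(rf, cloud, ground, mask, elevation, target)
  .job_assemble(job, .job_compute_cells(job, .job_cells(job)))
}

#' Dose rate at a single target cell
#'
#' Convenience single-cell forms of \code{\link{compute_dose_map}}.
#' \code{dose_at_cell} ignores obstacles, \code{dose_at_cell_attenuated}
#' applies the obstacle chord attenuation, and \code{dose_at_cell_elevated}
#' applies the terrain index offset (cloud shine only).
#'
#' @param i,j 1-based cell indices.
#' @inheritParams make_job
#' @return Dose rate (scalar), NA if the target cell is obstacle-occupied.
#' @export
dose_at_cell <- function(i, j, rf, cloud = NULL, ground = NULL) {
  m <- compute_dose_map(rf, cloud, ground, target = c(i, i, j, j))
  m$values[1L, 1L]
}

#' @rdname dose_at_cell
#' @export
dose_at_cell_attenuated <- function(i, j, rf, cloud = NULL, ground = NULL,
                                    mask = NULL) {
  m <- compute_dose_map(rf, cloud, ground, mask, target = c(i, i, j, j))
  m$values[1L, 1L]
}

#' @rdname dose_at_cell
#' @export
dose_at_cell_elevated <- function(i, j, rf, cloud, elevation) {
  m <- compute_dose_map(rf, cloud, elevation = elevation,
                        target = c(i, i, j, j))
  m$values[1L, 1L]
}

#' Obstacle chord length along a source-target ray
#'
#' Total length (m) of the straight segment between two points lying inside
#' obstacle-occupied voxels, by parametric voxel traversal; exact for
#' axis-aligned rays.
#'
#' @param src,tgt Numeric length-3 points (x, y, z) in m.
#' @param mask An \code{\link{obstacle_mask}}.
#' @export
obstacle_chord <- function(src, tgt, mask) {
  spec <- mask$spec
  .obstacle_chord_cpp(as.numeric(src), as.numeric(tgt),
                      as.integer(mask$occupied), dim(mask$occupied),
                      spec$x_min, spec$y_min, spec$dx,
                      as.numeric(spec$z_edges))
}
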