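## Cartesian grid data model: concentration, deposition, obstacles,
## elevation.  Cells are half-open intervals with centres at half steps;
## cell (i, j) centre = (x_min + (i - 0.5) dx, y_min + (j - 0.5) dx).

#' Grid specification
#'
#' @param x_min,y_min Lower-left corner of the domain, m.
#' @param dx Horizontal cell size, m (minimum resolution 1 m).
#' @param nx,ny Cell counts.
#' @param z_edges Vertical layer edges, m, strictly increasing from 0
#'   (supports non-uniform 1-4 m layering).
#' @export
grid_spec <- function(x_min, y_min, dx, nx, ny, z_edges = c(0, 1)) {
  if (dx < 1)
    .stop_cls("shinemap_resolution_error", "minimum resolution is 1 m")
  stopifnot(nx >= 1, ny >= 1, length(z_edges) >= 2,
            z_edges[1] == 0, !is.unsorted(z_edges, strictly = TRUE))
  structure(list(x_min = x_min, y_min = y_min, dx = dx,
                 nx = as.integer(nx), ny = as.integer(ny),
                 z_edges = as.numeric(z_edges)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells at %g m, origin (%g, %g), %d layers to %g m\n",
              x$nx, x$ny, x$dx, x$x_min, x$y_min,
              length(x$z_edges) - 1L, max(x$z_edges)))
  invisible(x)
}

.same_spec <- function(a, b) {
  isTRUE(all.equal(a[c("x_min", "y_min", "dx", "nx", "ny")],
                   b[c("x_min", "y_min", "dx", "nx", "ny")])) &&
    isTRUE(all.equal(a$z_edges, b$z_edges))
}

#' Layer centres / thicknesses of a grid
#' @param spec A \code{grid_spec}.
#' @export
layer_centers <- function(spec) {
  e <- spec$z_edges
  (e[-1] + e[-length(e)]) / 2
}

#' @rdname layer_centers
#' @export
layer_thickness <- function(spec) diff(spec$z_edges)

#' Three-dimensional activity-concentration field (kBq/m3 per cell)
#' @param spec A \code{grid_spec}.
#' @param values nx x ny x n_layers array, non-negative and finite.
#' @export
concentration_field <- function(spec, values) {
  values <- as.array(values)
  K <- length(spec$z_edges) - 1L
  if (!identical(dim(values), c(spec$nx, spec$ny, as.integer(K))))
    .stop_cls("shinemap_schema_error", "concentration dims must be (nx, ny, n_layers)")
  if (any(!is.finite(values)) || any(values < 0))
    .stop_cls("shinemap_schema_error", "concentration must be finite and >= 0")
  structure(list(spec = spec, values = values), class = "concentration_field")
}

#' Surface deposition (kBq/m2) with optional wall faces
#'
#' @param spec A \code{grid_spec}.
#' @param values nx x ny matrix of ground deposition, kBq/m2.
#' @param wall_faces Optional data.frame with columns \code{i, j, k}
#'   (1-based cell indices), \code{face} (one of "x-", "x+", "y-", "y+",
#'   "z+") and \code{value} (kBq/m2) for deposition on obstacle faces.
#' @export
surface_deposition <- function(spec, values, wall_faces = NULL) {
  values <- as.matrix(values)
  if (!identical(dim(values), c(spec$nx, spec$ny)))
    .stop_cls("shinemap_schema_error", "deposition dims must be (nx, ny)")
  if (any(!is.finite(values)) || any(values < 0))
    .stop_cls("shinemap_schema_error", "deposition must be finite and >= 0")
  if (!is.null(wall_faces)) {
    stopifnot(all(c("i", "j", "k", "face", "value") %in% names(wall_faces)),
              all(wall_faces$face %in% c("x-", "x+", "y-", "y+", "z+")),
              all(wall_faces$value >= 0))
  }
  structure(list(spec = spec, values = values, wall_faces = wall_faces),
            class = "surface_deposition")
}

#' Obstacle occupancy mask (single material)
#'
#' @param spec A \code{grid_spec}.
#' @param occupied nx x ny x n_layers logical array.
#' @param mu Linear dose-attenuation coefficient of the obstacle material,
#'   1/m (one material per simulation).
#' @export
obstacle_mask <- function(spec, occupied, mu) {
  occupied <- array(as.logical(occupied),
                    c(spec$nx, spec$ny, length(spec$z_edges) - 1L))
  stopifnot(mu >= 0)
  structure(list(spec = spec, occupied = occupied, mu = mu),
            class = "obstacle_mask")
}

#' Terrain elevation offsets (non-negative integer cells)
#'
#' @param spec A \code{grid_spec}.
#' @param offsets nx x ny matrix of non-negative integer cell offsets from
#'   the standard (lowest) level.
#' @param cell_size Vertical cell size the offsets are counted in, m.
#' @export
elevation_map <- function(spec, offsets, cell_size) {
  offsets <- matrix(as.integer(round(offsets)), spec$nx, spec$ny)
  if (any(offsets < 0) || min(offsets) != 0L)
    .stop_cls("shinemap_schema_error",
              "offsets must be >= 0 with minimum 0 (standard level)")
  stopifnot(cell_size > 0)
  structure(list(spec = spec, offsets = offsets, cell_size = cell_size),
            class = "elevation_map")
}

#' Convert a digital elevation model to cell offsets
#'
#' The standard level is the lowest elevation in the target area; offsets
#' are \code{round((h - min h)/cell_size)} with round-half-away-from-zero.
#'
#' @param heights nx x ny matrix of terrain heights, m.
#' @param cell_size Vertical cell size, m.
#' @param spec A \code{grid_spec}.
#' @export
elevation_from_dem <- function(heights, cell_size, spec) {
  h <- as.matrix(heights)
  stopifnot(all(is.finite(h)))
  off <- floor((h - min(h)) / cell_size + 0.5)   # round half away (h >= min)
  elevation_map(spec, off, cell_size)
}

.face_area <- function(spec, k, face) {
  th <- layer_thickness(spec)[k]
  ifelse(face == "z+", spec$dx^2, spec$dx * th)
}

#' Convert wall/roof deposition to adjacent-air concentration
#'
#' Deposition on obstacle faces (kBq/m2) is assigned to the neighbouring
#' atmospheric cell across each face as a concentration increment
#' \code{value * A_face / V_cell} (kBq/m3), conserving total activity.
#' Roof (\code{"z+"}) faces convert into the air cell above.
#'
#' @param dep A \code{\link{surface_deposition}} with \code{wall_faces}.
#' @param mask An \code{\link{obstacle_mask}} on the same grid.
#' @return A \code{\link{concentration_field}} of increments.
#' @export
wall_deposition_to_air <- function(dep, mask) {
  spec <- dep$spec
  if (!.same_spec(spec, mask$spec))
    .stop_cls("shinemap_config_error", "deposition and mask grids differ")
  K <- length(spec$z_edges) - 1L
  inc <- array(0, c(spec$nx, spec$ny, K))
  wf <- dep$wall_faces
  if (is.null(wf) || nrow(wf) == 0L) return(concentration_field(spec, inc))
  step <- list("x-" = c(-1L, 0L, 0L), "x+" = c(1L, 0L, 0L),
               "y-" = c(0L, -1L, 0L), "y+" = c(0L, 1L, 0L),
               "z+" = c(0L, 0L, 1L))
  orphans <- integer(0)
  for (r in seq_len(nrow(wf))) {
    if (!mask$occupied[wf$i[r], wf$j[r], wf$k[r]])
      .stop_cls("shinemap_schema_error",
                "wall face ", r, " does not reference an obstacle cell")
    s <- step[[wf$face[r]]]
    ni <- wf$i[r] + s[1L]; nj <- wf$j[r] + s[2L]; nk <- wf$k[r] + s[3L]
    if (ni < 1L || ni > spec$nx || nj < 1L || nj > spec$ny ||
        nk < 1L || nk > K || mask$occupied[ni, nj, nk]) {
      orphans <- c(orphans, r)
      next
    }
    A <- .face_area(spec, wf$k[r], wf$face[r])
    V <- spec$dx^2 * layer_thickness(spec)[nk]
    inc[ni, nj, nk] <- inc[ni, nj, nk] + wf$value[r] * A / V
  }
  if (length(orphans))
    .stop_cls("shinemap_orphan_face_error",
              "wall faces with no air neighbour: rows ",
              paste(orphans, collapse = ", "))
  concentration_field(spec, inc)
}

#' Change the horizontal resolution of a field
#'
#' Coarsening (integer ratio) uses the volume-weighted mean for
#' concentrations and the area-weighted mean for deposition; refining
#' (integer subdivision) replicates values.  Total activity is conserved in
#' both directions.  Grid extents must divide evenly.
#'
#' @param field A \code{concentration_field} or \code{surface_deposition}.
#' @param new_dx New cell size, m (>= 1).
#' @export
regrid <- function(field, new_dx) {
  spec <- field$spec
  if (new_dx < 1)
    .stop_cls("shinemap_resolution_error", "minimum resolution is 1 m")
  if (new_dx == spec$dx) return(field)
  coarsen <- new_dx > spec$dx
  ratio <- if (coarsen) new_dx / spec$dx else spec$dx / new_dx
  if (abs(ratio - round(ratio)) > 1e-9)
    .stop_cls("shinemap_resolution_error", "resolution ratio must be integer")
  k <- as.integer(round(ratio))
  if (coarsen && (spec$nx %% k != 0L || spec$ny %% k != 0L))
    .stop_cls("shinemap_resolution_error", "cell counts not divisible by ratio")
  nx2 <- if (coarsen) spec$nx %/% k else spec$nx * k
  ny2 <- if (coarsen) spec$ny %/% k else spec$ny * k
  spec2 <- grid_spec(spec$x_min, spec$y_min, new_dx, nx2, ny2, spec$z_edges)
  agg2d <- function(m) {
    if (coarsen) {
      s1 <- colSums(array(m, c(k, nx2, spec$ny)))         # (nx2, ny)
      s2 <- colSums(array(aperm(array(s1, c(nx2, k, ny2)),
                                c(2L, 1L, 3L)), c(k, nx2 * ny2)))
      matrix(s2, nx2, ny2) / (k * k)
    } else {
      m[rep(seq_len(spec$nx), each = k), rep(seq_len(spec$ny), each = k)]
    }
  }
  if (inherits(field, "concentration_field")) {
    K <- dim(field$values)[3L]
    out <- array(0, c(nx2, ny2, K))
    for (n in seq_len(K)) out[, , n] <- agg2d(field$values[, , n])
    concentration_field(spec2, out)
  } else if (inherits(field, "surface_deposition")) {
    surface_deposition(spec2, agg2d(field$values), field$wall_faces)
  } else .stop_cls("shinemap_config_error", "unsupported field type")
}

#' Total activity of a field (kBq)
#'
#' Concentration fields integrate C * cell volume; deposition integrates
#' ground values * cell area plus wall-face values * face area.
#' @param field A \code{concentration_field} or \code{surface_deposition}.
#' @export
total_activity <- function(field) {
  spec <- field$spec
  if (inherits(field, "concentration_field")) {
    th <- layer_thickness(spec)
    v <- 0
    for (n in seq_along(th))
      v <- v + sum(field$values[, , n]) * spec$dx^2 * th[n]
    return(v)
  }
  if (inherits(field, "surface_deposition")) {
    v <- sum(field$values) * spec$dx^2
    wf <- field$wall_faces
    if (!is.null(wf) && nrow(wf) > 0L)
      v <- v + sum(wf$value * .face_area(spec, wf$k, wf$face))
    return(v)
  }
  .stop_cls("shinemap_config_error", "unsupported field type")
}
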