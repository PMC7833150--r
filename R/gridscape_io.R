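## Readers/writers for gridded fields.  NetCDF dialect: variables
## air_concentration(z,y,x) [kBq/m3], deposition(y,x) [kBq/m2],
## obstacle(z,y,x) [0/1], elevation(y,x) [cells]; dimension variables x, y
## carry cell-centre coordinates and z_edges the layer interfaces.  The CSV
## dialect covers 2-D fields only.

.FACE_CODE <- c("x-" = 1L, "x+" = 2L, "y-" = 3L, "y+" = 4L, "z+" = 5L)

#' Write fields to a NetCDF file
#'
#' @param path Output path.
#' @param conc Optional \code{\link{concentration_field}}.
#' @param dep Optional \code{\link{surface_deposition}}.
#' @param mask Optional \code{\link{obstacle_mask}}.
#' @param elev Optional \code{\link{elevation_map}}.
#' @export
write_fields <- function(path, conc = NULL, dep = NULL, mask = NULL,
                         elev = NULL) {
  given <- Filter(Negate(is.null), list(conc, dep, mask, elev))
  if (!length(given)) .stop_cls("shinemap_config_error", "nothing to write")
  spec <- given[[1L]]$spec
  xc <- spec$x_min + (seq_len(spec$nx) - 0.5) * spec$dx
  yc <- spec$y_min + (seq_len(spec$ny) - 0.5) * spec$dx
  K <- length(spec$z_edges) - 1L
  dim_x <- ncdim_def("x", "m", xc)
  dim_y <- ncdim_def("y", "m", yc)
  dim_z <- ncdim_def("z", "m", layer_centers(spec))
  dim_e <- ncdim_def("z_edge", "m", spec$z_edges)
  vars <- list(ncvar_def("z_edges", "m", dim_e, prec = "double"))
  if (!is.null(conc))
    vars <- c(vars, list(ncvar_def("air_concentration", "kBq/m3",
                                   list(dim_x, dim_y, dim_z), prec = "double")))
  if (!is.null(dep)) {
    vars <- c(vars, list(ncvar_def("deposition", "kBq/m2",
                                   list(dim_x, dim_y), prec = "double")))
    wf <- dep$wall_faces
    if (!is.null(wf) && nrow(wf) > 0L) {
      dim_w <- ncdim_def("nwall", "", seq_len(nrow(wf)))
      vars <- c(vars,
                list(ncvar_def("wall_i", "", dim_w, prec = "integer"),
                     ncvar_def("wall_j", "", dim_w, prec = "integer"),
                     ncvar_def("wall_k", "", dim_w, prec = "integer"),
                     ncvar_def("wall_face", "", dim_w, prec = "integer"),
                     ncvar_def("wall_value", "kBq/m2", dim_w, prec = "double")))
    }
  }
  if (!is.null(mask))
    vars <- c(vars, list(ncvar_def("obstacle", "",
                                   list(dim_x, dim_y, dim_z), prec = "integer")))
  if (!is.null(elev))
    vars <- c(vars, list(ncvar_def("elevation", "cells",
                                   list(dim_x, dim_y), prec = "integer")))
  nc <- nc_create(path, vars)
  on.exit(nc_close(nc))
  ncvar_put(nc, "z_edges", spec$z_edges)
  ncatt_put(nc, 0, "x_min", spec$x_min, prec = "double")
  ncatt_put(nc, 0, "y_min", spec$y_min, prec = "double")
  ncatt_put(nc, 0, "dx", spec$dx, prec = "double")
  if (!is.null(conc)) ncvar_put(nc, "air_concentration", conc$values)
  if (!is.null(dep)) {
    ncvar_put(nc, "deposition", dep$values)
    wf <- dep$wall_faces
    if (!is.null(wf) && nrow(wf) > 0L) {
      ncvar_put(nc, "wall_i", wf$i); ncvar_put(nc, "wall_j", wf$j)
      ncvar_put(nc, "wall_k", wf$k)
      ncvar_put(nc, "wall_face", unname(.FACE_CODE[wf$face]))
      ncvar_put(nc, "wall_value", wf$value)
    }
  }
  if (!is.null(mask)) {
    ncvar_put(nc, "obstacle", array(as.integer(mask$occupied), dim(mask$occupied)))
    ncatt_put(nc, "obstacle", "mu_per_m", mask$mu, prec = "double")
  }
  if (!is.null(elev)) {
    ncvar_put(nc, "elevation", elev$offsets)
    ncatt_put(nc, "elevation", "cell_size_m", elev$cell_size, prec = "double")
  }
  invisible(path)
}

.require_var <- function(nc, name) {
  if (!name %in% names(nc$var) && !name %in% names(nc$dim))
    .stop_cls("shinemap_schema_error", "missing variable: ", name)
}

.check_units <- function(nc, var, expected) {
  u <- ncatt_get(nc, var, "units")
  if (!isTRUE(u$hasatt) || !identical(u$value, expected))
    .stop_cls("shinemap_schema_error", "variable ", var,
              " must carry units ", expected)
}

#' Read fields written by \code{\link{write_fields}} (NetCDF dialect) or
#' a 2-D CSV field
#'
#' @param path File path.
#' @param dialect \code{"netcdf"} or \code{"csv"}.
#' @return For NetCDF: list with any of \code{conc}, \code{dep},
#'   \code{mask}, \code{elev} on a validated common \code{grid_spec}.  For
#'   CSV (2-D only): a \code{surface_deposition}.
#' @export
read_fields <- function(path, dialect = c("netcdf", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") return(.read_csv_field(path))
  nc <- nc_open(path)
  on.exit(nc_close(nc))
  for (d in c("x", "y")) {
    if (!d %in% names(nc$dim))
      .stop_cls("shinemap_schema_error", "missing dimension: ", d)
  }
  xc <- nc$dim$x$vals
  yc <- nc$dim$y$vals
  g <- ncatt_get(nc, 0, "dx")
  dx <- if (isTRUE(g$hasatt)) g$value else diff(xc[1:2])
  x_min <- ncatt_get(nc, 0, "x_min")$value
  y_min <- ncatt_get(nc, 0, "y_min")$value
  .require_var(nc, "z_edges")
  z_edges <- as.numeric(ncvar_get(nc, "z_edges"))
  spec <- grid_spec(x_min, y_min, dx, length(xc), length(yc), z_edges)
  out <- list(spec = spec)
  if ("air_concentration" %in% names(nc$var)) {
    .check_units(nc, "air_concentration", "kBq/m3")
    v <- ncvar_get(nc, "air_concentration", collapse_degen = FALSE)
    if (any(v < 0))
      .stop_cls("shinemap_schema_error", "negative concentrations")
    out$conc <- concentration_field(spec, array(v, c(spec$nx, spec$ny,
                                                     length(z_edges) - 1L)))
  }
  if ("deposition" %in% names(nc$var)) {
    .check_units(nc, "deposition", "kBq/m2")
    v <- ncvar_get(nc, "deposition", collapse_degen = FALSE)
    if (any(v < 0)) .stop_cls("shinemap_schema_error", "negative deposition")
    wf <- NULL
    if ("wall_value" %in% names(nc$var)) {
      wf <- data.frame(i = as.integer(ncvar_get(nc, "wall_i")),
                       j = as.integer(ncvar_get(nc, "wall_j")),
                       k = as.integer(ncvar_get(nc, "wall_k")),
                       face = names(.FACE_CODE)[as.integer(ncvar_get(nc, "wall_face"))],
                       value = as.numeric(ncvar_get(nc, "wall_value")))
    }
    out$dep <- surface_deposition(spec, matrix(v, spec$nx, spec$ny), wf)
  }
  if ("obstacle" %in% names(nc$var)) {
    v <- ncvar_get(nc, "obstacle", collapse_degen = FALSE)
    mu <- ncatt_get(nc, "obstacle", "mu_per_m")$value
    out$mask <- obstacle_mask(spec, array(v != 0, dim(v)), mu)
  }
  if ("elevation" %in% names(nc$var)) {
    v <- ncvar_get(nc, "elevation", collapse_degen = FALSE)
    cs <- ncatt_get(nc, "elevation", "cell_size_m")$value
    out$elev <- elevation_map(spec, matrix(v, spec$nx, spec$ny), cs)
  }
  out
}

#' Write a 2-D field (deposition or dose values) as CSV
#'
#' Long format with columns x, y, value; grid metadata in '#' comment
#' header lines.
#' @param field A \code{surface_deposition}.
#' @param path Output path.
#' @export
write_csv_field <- function(field, path) {
  spec <- field$spec
  xc <- spec$x_min + (seq_len(spec$nx) - 0.5) * spec$dx
  yc <- spec$y_min + (seq_len(spec$ny) - 0.5) * spec$dx
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# shinemap 2-D field; units kBq/m2"),
               sprintf("# x_min %g y_min %g dx %g nx %d ny %d",
                       spec$x_min, spec$y_min, spec$dx, spec$nx, spec$ny)), con)
  df <- data.frame(x = rep(xc, times = spec$ny),
                   y = rep(yc, each = spec$nx),
                   value = as.vector(field$values))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.read_csv_field <- function(path) {
  hdr <- readLines(path, n = 2L)
  if (length(hdr) < 2L || !startsWith(hdr[1L], "#"))
    .stop_cls("shinemap_schema_error", "missing CSV field header")
  meta <- strsplit(sub("^# ", "", hdr[2L]), " ")[[1L]]
  val <- function(key) as.numeric(meta[match(key, meta) + 1L])
  spec <- grid_spec(val("x_min"), val("y_min"), val("dx"),
                    as.integer(val("nx")), as.integer(val("ny")))
  df <- read.csv(path, comment.char = "#")
  if (!all(c("x", "y", "value") %in% names(df)))
    .stop_cls("shinemap_schema_error", "CSV field needs x, y, value columns")
  if (any(df$value < 0))
    .stop_cls("shinemap_schema_error", "negative values in CSV field")
  surface_deposition(spec, matrix(df$value, spec$nx, spec$ny))
}

#' Write a dose map
#'
#' CSV (x, y, value, skipped) or NetCDF (dose(y,x) plus skip mask) with a
#' units attribute (mSv/h for H*(10), mGy/h for air kerma).
#' @param map A \code{dose_map}.
#' @param path Output path.
#' @param format \code{"csv"} or \code{"netcdf"}.
#' @export
write_dose_map <- function(map, path, format = c("csv", "netcdf")) {
  format <- match.arg(format)
  units <- if (identical(map$quantity, "kerma")) "mGy/h" else "mSv/h"
  spec <- map$spec
  xc <- spec$x_min + (map$window[1L]:map$window[2L] - 0.5) * spec$dx
  yc <- spec$y_min + (map$window[3L]:map$window[4L] - 0.5) * spec$dx
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# shinemap dose map; units %s; nuclide %s",
                       units, map$nuclide), con)
    df <- data.frame(x = rep(xc, times = length(yc)),
                     y = rep(yc, each = length(xc)),
                     value = ifelse(is.na(as.vector(map$values)), 0,
                                    as.vector(map$values)),
                     skipped = as.vector(map$skipped))
    write.csv(df, con, row.names = FALSE)
    return(invisible(path))
  }
  dim_x <- ncdim_def("x", "m", xc)
  dim_y <- ncdim_def("y", "m", yc)
  v_d <- ncvar_def("dose", units, list(dim_x, dim_y), prec = "double")
  v_s <- ncvar_def("skipped", "", list(dim_x, dim_y), prec = "integer")
  nc <- nc_create(path, list(v_d, v_s))
  on.exit(nc_close(nc))
  vals <- map$values
  vals[is.na(vals)] <- 0
  ncvar_put(nc, "dose", vals)
  ncvar_put(nc, "skipped", array(as.integer(map$skipped), dim(map$skipped)))
  ncatt_put(nc, 0, "nuclide", map$nuclide)
  invisible(path)
}

#' Read a CSV dose map written by \code{\link{write_dose_map}}
#' @param path File path.
#' @return data.frame with x, y, value, skipped.
#' @export
read_dose_map <- function(path) {
  read.csv(path, comment.char = "#")
}
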