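## Synthetic fixtures: the steady Gaussian-plume cases over flat and
## stepped terrain, and an unsteady building-array release emulated by a
## seeded Gaussian-puff surrogate with dry deposition on ground, walls and
## roofs.  The surrogate produces fields with the right structure (a plume
## tracking through the array, deposition hotspots near the release) but
## makes no claim of fidelity to a large-eddy simulation.

#' Configuration for the steady-plume cases
#'
#' Variant A: 2-km square target at 5-m resolution, flat terrain.
#' Variant B: x in [-1, 10] km, y in [-10, 10] km at 100-m resolution,
#' flat.  Variant C: as B with terrain steps of 10 m (2 km <= x < 4 km)
#' and 30 m (x >= 4 km), 10-m vertical cells (offsets 0/1/3).  All use a
#' 85Kr release (cloud shine only) with Q = 1 Bq/s, U = 1 m/s, H = 150 m.
#'
#' @param variant \code{"A"}, \code{"B"} or \code{"C"}.
#' @param resolution Optional override of the horizontal resolution (m)
#'   for reduced-size runs; must divide the full extents.
#' @param stability_class Pasquill class (default neutral "D"; the
#'   dispersion curves are a package choice, see the methods vignette).
#' @return A \code{scenario_config} list, serialisable to YAML.
#' @export
make_case1 <- function(variant = c("A", "B", "C"), resolution = NULL,
                       stability_class = "D") {
  variant <- match.arg(variant)
  full_res <- if (variant == "A") 5 else 100
  res <- if (is.null(resolution)) full_res else resolution
  ext <- if (variant == "A") list(x = c(-1000, 1000), y = c(-1000, 1000))
         else list(x = c(-1000, 10000), y = c(-10000, 10000))
  z_top <- 320
  cfg <- list(
    case = paste0("1", variant),
    nuclide = "85Kr",
    quantity = "hstar10",
    plume = list(Q = 1, U = 1, H = 150, stability_class = stability_class),
    resolution = res,
    extent = ext,
    z_step = if (variant == "A") 20 else 40,
    z_top = z_top,
    elevation = if (variant == "C")
      list(steps = list(list(from_x = 2000, to_x = 4000, height = 10),
                        list(from_x = 4000, to_x = 10000, height = 30)),
           cell_size = 10)
    else NULL,
    seed = 0L)
  class(cfg) <- c("scenario_config", "list")
  cfg
}

#' Generate the gridded fields of a steady-plume case
#'
#' @param cfg A \code{\link{make_case1}} configuration.
#' @return List with \code{spec}, \code{cloud} (cell-integrated
#'   \code{concentration_field}) and optional \code{elev}.
#' @export
case1_fields <- function(cfg) {
  res <- cfg$resolution
  nx <- as.integer(round(diff(cfg$extent$x) / res))
  ny <- as.integer(round(diff(cfg$extent$y) / res))
  spec <- grid_spec(cfg$extent$x[1], cfg$extent$y[1], res, nx, ny,
                    z_edges = seq(0, cfg$z_top, by = cfg$z_step))
  pp <- plume_parameters(cfg$plume$Q, cfg$plume$U, cfg$plume$H,
                         cfg$plume$stability_class)
  cloud <- cell_integrated_grid(pp, spec)
  elev <- NULL
  if (!is.null(cfg$elevation)) {
    xc <- spec$x_min + (seq_len(nx) - 0.5) * res
    h <- numeric(nx)
    for (s in cfg$elevation$steps)
      h[xc >= s$from_x & xc <= s$to_x] <- s$height
    heights <- matrix(h, nx, ny)
    elev <- elevation_from_dem(heights, cfg$elevation$cell_size, spec)
  }
  list(spec = spec, cloud = cloud, elev = elev, config = cfg)
}

.building_edges <- function(resolution) {
  if (resolution <= 1) c(0:24, seq(26, 40, 2), seq(44, 148, 4), 150)
  else if (resolution == 2) c(seq(0, 24, 2), seq(28, 48, 4), seq(56, 144, 8), 150)
  else c(seq(0, 24, 4), 32, 40, 56, 80, 120, 150)
}

.building_mask <- function(spec) {
  centers <- c(-96, -48, 0, 48, 96)
  xc <- spec$x_min + (seq_len(spec$nx) - 0.5) * spec$dx
  yc <- spec$y_min + (seq_len(spec$ny) - 0.5) * spec$dx
  inb <- function(v) {
    out <- rep(FALSE, length(v))
    for (c0 in centers) out <- out | (v > c0 - 12 & v < c0 + 12)
    out
  }
  K <- length(spec$z_edges) - 1L
  occ <- array(FALSE, c(spec$nx, spec$ny, K))
  kz <- which(spec$z_edges[-1] <= 24)           # layers fully below roof
  footprint <- outer(inb(xc), inb(yc), `&`)
  for (k in kz) occ[, , k] <- footprint
  occ
}

.wall_face_table <- function(spec, occ) {
  K <- dim(occ)[3L]
  faces <- list()
  shift <- function(a, di, dj, dk) {
    nx <- dim(a)[1L]; ny <- dim(a)[2L]; nz <- dim(a)[3L]
    out <- array(FALSE, dim(a))
    ii <- seq_len(nx); jj <- seq_len(ny); kk <- seq_len(nz)
    si <- ii + di; sj <- jj + dj; sk <- kk + dk
    vi <- si >= 1 & si <= nx; vj <- sj >= 1 & sj <= ny; vk <- sk >= 1 & sk <= nz
    out[ii[vi], jj[vj], kk[vk]] <- a[si[vi], sj[vj], sk[vk]]
    out
  }
  for (f in names(.FACE_CODE)) {
    d <- switch(f, "x-" = c(-1L, 0L, 0L), "x+" = c(1L, 0L, 0L),
                "y-" = c(0L, -1L, 0L), "y+" = c(0L, 1L, 0L),
                "z+" = c(0L, 0L, 1L))
    nb_air <- !shift(occ, d[1L], d[2L], d[3L])
    ## neighbour index must also be inside the grid
    inside <- array(TRUE, dim(occ))
    if (d[1L] == -1L) inside[1L, , ] <- FALSE
    if (d[1L] == 1L) inside[dim(occ)[1L], , ] <- FALSE
    if (d[2L] == -1L) inside[, 1L, ] <- FALSE
    if (d[2L] == 1L) inside[, dim(occ)[2L], ] <- FALSE
    if (d[3L] == 1L) inside[, , K] <- FALSE
    sel <- which(occ & nb_air & inside, arr.ind = TRUE)
    if (nrow(sel))
      faces[[f]] <- data.frame(i = sel[, 1L], j = sel[, 2L], k = sel[, 3L],
                               face = f, value = 0)
  }
  do.call(rbind, c(faces, list(make.row.names = FALSE)))
}

#' Synthetic building-array scenario
#'
#' A 240 m x 240 m x 150 m domain with a 5 x 5 regular array of 24-m cubic
#' buildings (mixture of 90\% air / 10\% concrete, bulk density 0.24 g/cm3,
#' linear dose-attenuation coefficient 1.85 1/m) over flat terrain.  A
#' seeded Gaussian-puff surrogate releases 347.25 Bq of 137Cs at
#' (-36, 0, 0), advects it in +x with crosswind meander, and accumulates
#' dry deposition at 0.1 cm/s on the ground and 0.05 cm/s on building walls
#' and roofs.  Two snapshots are returned: an airborne ("2A-like") cloud
#' and a deposition ("2B-like") surface field; airborne + deposited
#' activity equals 347.25 Bq at every snapshot by construction.
#'
#' @param seed Integer seed fixing the crosswind meander.
#' @param resolution Horizontal resolution, m (1, 2 or 4; 4 is the reduced
#'   default, 1 the full fidelity of the emulated geometry).
#' @param t_cloud,t_dep Snapshot times, s (nominal labels for the airborne
#'   and deposition snapshots).
#' @param dt Deposition integration step, s.
#' @param include_roof Include roof (\code{"z+"}) faces in the deposition
#'   table (default TRUE).
#' @return List with \code{config}, \code{spec}, \code{mask} (mu = 1.85
#'   1/m), \code{cloud} (2A-like), \code{deposition} (2B-like, with wall
#'   faces), \code{cloud_residual} (airborne field at the deposition
#'   snapshot), and the activity ledger \code{totals} (kBq).
#' @export
make_building_array <- function(seed = 1L, resolution = 4,
                                t_cloud = 720, t_dep = 1800, dt = 10,
                                include_roof = TRUE) {
  stopifnot(resolution %in% c(1, 2, 4))
  spec <- grid_spec(-120, -120, resolution,
                    240 / resolution, 240 / resolution,
                    .building_edges(resolution))
  occ <- .building_mask(spec)
  mask <- obstacle_mask(spec, occ, mu = 1.85)
  wf <- .wall_face_table(spec, occ)
  if (!include_roof) wf <- wf[wf$face != "z+", ]
  A0 <- 0.34725                                  # kBq (= 347.25 Bq)
  u <- 0.15                                      # m/s effective advection
  set.seed(seed)
  n_steps <- ceiling(t_dep / dt)
  meander <- cumsum(rnorm(n_steps + 1L, 0, 0.8))  # crosswind random walk, m

  xc <- spec$x_min + (seq_len(spec$nx) - 0.5) * spec$dx
  yc <- spec$y_min + (seq_len(spec$ny) - 0.5) * spec$dx
  zc <- layer_centers(spec)
  th <- layer_thickness(spec)
  K <- length(zc)

  puff <- function(t, x, y, z) {
    d <- u * t
    s_h <- 2 + 0.25 * d
    s_z <- 1 + 0.15 * d
    zcn <- 1 + 0.05 * d
    x0 <- -36 + d
    y0 <- meander[pmin(floor(t / dt) + 1L, n_steps + 1L)]
    (exp(-(x - x0)^2 / (2 * s_h^2)) / (sqrt(2 * pi) * s_h)) *
      (exp(-(y - y0)^2 / (2 * s_h^2)) / (sqrt(2 * pi) * s_h)) *
      ((exp(-(z - zcn)^2 / (2 * s_z^2)) + exp(-(z + zcn)^2 / (2 * s_z^2))) /
         (sqrt(2 * pi) * s_z))
  }

  ## discretised in-domain cloud field (kBq/m3) normalised to carry
  ## exactly `airborne` kBq outside the buildings
  snapshot_cloud <- function(t, airborne) {
    vals <- array(0, c(spec$nx, spec$ny, K))
    X <- matrix(xc, spec$nx, spec$ny)
    Y <- matrix(yc, spec$nx, spec$ny, byrow = TRUE)
    for (k in seq_len(K)) {
      v <- puff(t, X, Y, zc[k])
      v[occ[, , k]] <- 0
      vals[, , k] <- v
    }
    tot <- 0
    for (k in seq_len(K)) tot <- tot + sum(vals[, , k]) * spec$dx^2 * th[k]
    if (tot > 0) vals <- vals * (airborne / tot)
    concentration_field(spec, vals)
  }

  ## deposition bookkeeping
  ground_open <- !occ[, , 1L]
  dep_ground <- matrix(0, spec$nx, spec$ny)
  wall_vals <- numeric(nrow(wf))
  v_ground <- 0.1 / 100                          # m/s
  v_wall <- 0.05 / 100
  face_area <- .face_area(spec, wf$k, wf$face)
  ## face-centre coordinates for concentration sampling
  fx <- xc[wf$i] + ifelse(wf$face == "x-", -spec$dx / 2,
                   ifelse(wf$face == "x+", spec$dx / 2, 0))
  fy <- yc[wf$j] + ifelse(wf$face == "y-", -spec$dx / 2,
                   ifelse(wf$face == "y+", spec$dx / 2, 0))
  fz <- ifelse(wf$face == "z+", spec$z_edges[wf$k + 1L], zc[wf$k])
  Xg <- matrix(xc, spec$nx, spec$ny)
  Yg <- matrix(yc, spec$nx, spec$ny, byrow = TRUE)

  deposited <- 0
  airborne <- A0
  snap_cloud <- NULL
  airborne_at_cloud <- NA_real_
  for (s in seq_len(n_steps)) {
    t <- s * dt
    shape_g <- puff(t, Xg, Yg, 0)
    shape_g[!ground_open] <- 0
    shape_w <- puff(t, fx, fy, fz)
    conc_scale <- airborne                       # kBq/m3 per unit shape
    inc_g <- v_ground * conc_scale * shape_g * dt          # kBq/m2
    inc_w <- v_wall * conc_scale * shape_w * dt
    removed <- sum(inc_g) * spec$dx^2 + sum(inc_w * face_area)
    if (removed > airborne) {                    # cannot deposit more than is airborne
      f <- airborne / removed
      inc_g <- inc_g * f; inc_w <- inc_w * f; removed <- airborne
    }
    dep_ground <- dep_ground + inc_g
    wall_vals <- wall_vals + inc_w
    deposited <- deposited + removed
    airborne <- A0 - deposited
    if (abs(t - t_cloud) < dt / 2 && is.null(snap_cloud)) {
      snap_cloud <- snapshot_cloud(t, airborne)
      airborne_at_cloud <- airborne
    }
  }
  if (is.null(snap_cloud)) {
    snap_cloud <- snapshot_cloud(t_cloud, airborne)
    airborne_at_cloud <- airborne
  }
  wf$value <- wall_vals
  dep <- surface_deposition(spec, dep_ground, wf)
  cfg <- list(case = "building_array", nuclide = "137Cs",
              quantity = "hstar10", seed = as.integer(seed),
              resolution = resolution, mu = 1.85,
              total_activity_kBq = A0, u = u,
              v_dep_ground_cm_s = 0.1, v_dep_wall_cm_s = 0.05,
              t_cloud = t_cloud, t_dep = t_dep, dt = dt,
              include_roof = include_roof)
  class(cfg) <- c("scenario_config", "list")
  list(config = cfg, spec = spec, mask = mask,
       cloud = snap_cloud,
       deposition = dep,
       cloud_residual = snapshot_cloud(t_dep, airborne),
       totals = list(initial = A0,
                     airborne_at_cloud = airborne_at_cloud,
                     airborne_at_dep = airborne,
                     deposited_at_dep = deposited))
}
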