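## Analytic steady-state Gaussian plume source term with ground reflection
## and Briggs open-country dispersion curves per Pasquill stability class.

.BRIGGS <- list(
  A = list(sy = c(0.22, 1e-4, -0.5), sz = c(0.20, 0,      0)),
  B = list(sy = c(0.16, 1e-4, -0.5), sz = c(0.12, 0,      0)),
  C = list(sy = c(0.11, 1e-4, -0.5), sz = c(0.08, 2e-4,  -0.5)),
  D = list(sy = c(0.08, 1e-4, -0.5), sz = c(0.06, 1.5e-3, -0.5)),
  E = list(sy = c(0.06, 1e-4, -0.5), sz = c(0.03, 3e-4,  -1)),
  F = list(sy = c(0.04, 1e-4, -0.5), sz = c(0.016, 3e-4, -1)))

#' Gaussian plume parameters
#'
#' @param Q Emission rate, Bq/s (>= 0).
#' @param U Mean wind speed along the plume centreline, m/s (> 0).
#' @param H Effective release height, m (>= 0).
#' @param stability_class Pasquill stability class, one of \code{"A"}
#'   (most unstable) to \code{"F"} (most stable).
#' @return Object of class \code{plume_parameters}.
#' @export
plume_parameters <- function(Q = 1, U = 1, H = 150, stability_class = "D") {
  stopifnot(Q >= 0, U > 0, H >= 0)
  stability_class <- match.arg(stability_class, names(.BRIGGS))
  structure(list(Q = Q, U = U, H = H, stability_class = stability_class),
            class = "plume_parameters")
}

#' Dispersion standard deviations
#'
#' Briggs open-country interpolation formulas,
#' \eqn{\sigma = a x (1 + b x)^c}, adopted as the closed-form rendering of
#' the Pasquill-Gifford curves.
#'
#' @param x Downwind distance, m (> 0; vectorised).
#' @param stability_class Pasquill class A-F.
#' @return List with components \code{sigma_y} and \code{sigma_z} (m).
#' @export
sigma_yz <- function(x, stability_class = "D") {
  if (any(x <= 0))
    .stop_cls("shinemap_domain_error", "downwind distance must be > 0")
  cf <- .BRIGGS[[match.arg(stability_class, names(.BRIGGS))]]
  list(sigma_y = cf$sy[1] * x * (1 + cf$sy[2] * x)^cf$sy[3],
       sigma_z = cf$sz[1] * x * (1 + cf$sz[2] * x)^cf$sz[3])
}

#' Gaussian plume concentration
#'
#' Steady-state plume with total ground reflection:
#' \deqn{C = \frac{Q}{2\pi\sigma_y\sigma_z U} e^{-y^2/2\sigma_y^2}
#'   \left[e^{-(z-H)^2/2\sigma_z^2} + e^{-(z+H)^2/2\sigma_z^2}\right].}
#' Upwind of the source (x <= 0) the concentration is defined as 0.
#'
#' @param params \code{\link{plume_parameters}}.
#' @param x,y,z Coordinates in m (vectorised; x downwind, y crosswind,
#'   z height >= 0).
#' @return Concentration in Bq/m3.
#' @export
concentration_at <- function(params, x, y, z) {
  stopifnot(inherits(params, "plume_parameters"))
  if (any(z < 0)) .stop_cls("shinemap_domain_error", "z must be >= 0")
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  out <- numeric(n)
  ok <- x > 0
  if (any(ok)) {
    s <- sigma_yz(x[ok], params$stability_class)
    out[ok] <- params$Q / (2 * pi * s$sigma_y * s$sigma_z * params$U) *
      exp(-y[ok]^2 / (2 * s$sigma_y^2)) *
      (exp(-(z[ok] - params$H)^2 / (2 * s$sigma_z^2)) +
       exp(-(z[ok] + params$H)^2 / (2 * s$sigma_z^2)))
  }
  out
}

#' Cell-integrated plume concentrations on a grid
#'
#' Per-cell mean concentration by 3-point Gauss-Legendre quadrature per
#' dimension over each cell volume.  Quadrature nodes at x <= 0 contribute
#' zero; cells whose centre lies at x <= 0 are flagged upwind.
#'
#' @param params \code{\link{plume_parameters}}.
#' @param spec A \code{\link{grid_spec}}.
#' @return A \code{\link{concentration_field}} (kBq/m3) with an
#'   \code{upwind} attribute (logical nx x ny matrix).
#' @export
cell_integrated_grid <- function(params, spec) {
  stopifnot(inherits(spec, "grid_spec"))
  gx <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)) / 2   # on [-1/2, 1/2]
  gw <- c(5, 8, 5) / 18
  xc <- spec$x_min + (seq_len(spec$nx) - 0.5) * spec$dx
  yc <- spec$y_min + (seq_len(spec$ny) - 0.5) * spec$dx
  zc <- layer_centers(spec)
  th <- layer_thickness(spec)
  K <- length(zc)
  vals <- array(0, c(spec$nx, spec$ny, K))
  X <- array(rep(xc, times = spec$ny * K), c(spec$nx, spec$ny, K))
  Y <- array(rep(rep(yc, each = spec$nx), times = K), c(spec$nx, spec$ny, K))
  Z <- array(rep(zc, each = spec$nx * spec$ny), c(spec$nx, spec$ny, K))
  TH <- array(rep(th, each = spec$nx * spec$ny), c(spec$nx, spec$ny, K))
  for (ix in 1:3) for (iy in 1:3) for (iz in 1:3) {
    w <- gw[ix] * gw[iy] * gw[iz]
    zq <- pmax(Z + gx[iz] * TH, 0)
    vals <- vals + w * concentration_at(params, X + gx[ix] * spec$dx,
                                        Y + gx[iy] * spec$dx, zq)
  }
  upwind <- outer(xc, yc, function(a, b) a <= 0)
  f <- concentration_field(spec, vals / 1000)   # Bq/m3 -> kBq/m3
  attr(f, "upwind") <- upwind
  f
}
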