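## Packaged photon physics: decay lines, attenuation, buildup, dose conversion.

.shinemap <- new.env(parent = emptyenv())

.data_file <- function(name) {
  path <- system.file("extdata", name, package = "shinemap")
  if (!nzchar(path)) stop("packaged data file not found: ", name)
  path
}

.read_table <- function(name, col.names) {
  key <- paste0("tab_", name)
  if (!is.null(.shinemap[[key]])) return(.shinemap[[key]])
  tab <- read.table(.data_file(name), header = FALSE, comment.char = "#",
                    col.names = col.names, stringsAsFactors = FALSE)
  .shinemap[[key]] <- tab
  tab
}

.stop_cls <- function(class, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Log-log interpolation in energy-indexed tables
#'
#' Linear interpolation of log(value) against log(energy); standard practice
#' for photon cross-section and conversion-coefficient tables.  Energies
#' outside the node range raise a range error.
#' @noRd
.loglog_interp <- function(energy, nodes, values) {
  if (any(energy < nodes[1L] | energy > nodes[length(nodes)]))
    .stop_cls("shinemap_range_error",
              "energy ", paste(energy[energy < nodes[1L] | energy > nodes[length(nodes)]][1L]),
              " keV outside table range [", nodes[1L], ", ", nodes[length(nodes)], "]")
  exp(approx(log(nodes), log(values), xout = log(energy), ties = "ordered")$y)
}

#' Supported radionuclides
#'
#' @return Character vector of the nuclide identifiers the package ships
#'   decay data for.
#' @export
supported_nuclides <- function() {
  .read_table("nuclides.txt", c("nuclide", "noble_gas", "progeny_note"))$nuclide
}

#' Nuclide metadata
#'
#' @param nuclide Nuclide identifier, e.g. \code{"137Cs"}.
#' @return List with \code{name}, \code{is_noble_gas}, \code{progeny_note}
#'   and the \code{lines} data frame (energy_keV, intensity).
#' @export
nuclide_info <- function(nuclide) {
  tab <- .read_table("nuclides.txt", c("nuclide", "noble_gas", "progeny_note"))
  i <- match(nuclide, tab$nuclide)
  if (is.na(i))
    .stop_cls("shinemap_unsupported_nuclide", "unsupported nuclide: ", nuclide)
  list(name = nuclide,
       is_noble_gas = identical(tab$noble_gas[i], "yes"),
       progeny_note = tab$progeny_note[i],
       lines = gamma_lines(nuclide))
}

#' Gamma emission lines of a nuclide
#'
#' Returns the packaged principal gamma lines (photons per decay).  For
#' 137Cs the 661.66 keV line of the 137mBa progeny in equilibrium is
#' included.
#'
#' @inheritParams nuclide_info
#' @return data.frame with columns \code{energy_keV} and \code{intensity},
#'   plus attribute \code{is_noble_gas}.
#' @export
gamma_lines <- function(nuclide) {
  nucs <- .read_table("nuclides.txt", c("nuclide", "noble_gas", "progeny_note"))
  i <- match(nuclide, nucs$nuclide)
  if (is.na(i))
    .stop_cls("shinemap_unsupported_nuclide", "unsupported nuclide: ", nuclide)
  tab <- .read_table("gamma_lines.txt", c("nuclide", "energy_keV", "intensity"))
  lines <- tab[tab$nuclide == nuclide, c("energy_keV", "intensity")]
  rownames(lines) <- NULL
  stopifnot(nrow(lines) > 0L, all(lines$energy_keV > 0),
            all(lines$intensity > 0), all(lines$intensity <= 1))
  attr(lines, "is_noble_gas") <- identical(nucs$noble_gas[i], "yes")
  lines
}

.default_density <- c(air = 1.205e-3, soil = 1.6, concrete = 2.3)

#' Define a material mixture by volume fractions
#'
#' Mixture mass attenuation is combined by mass-fraction weighting of the
#' component coefficients; component densities default to the packaged bulk
#' densities (air 1.205e-3, soil 1.6, concrete 2.3 g/cm3).
#'
#' @param volume_fractions Named numeric vector of volume fractions, e.g.
#'   \code{c(concrete = 0.1, air = 0.9)}.  Must sum to 1.
#' @param densities Optional named numeric vector of component densities
#'   (g/cm3) overriding the defaults.
#' @return Object of class \code{shinemap_mixture}.
#' @export
mixture <- function(volume_fractions, densities = NULL) {
  stopifnot(!is.null(names(volume_fractions)),
            all(names(volume_fractions) %in% names(.default_density)),
            abs(sum(volume_fractions) - 1) < 1e-9,
            all(volume_fractions >= 0))
  dens <- .default_density[names(volume_fractions)]
  if (!is.null(densities)) dens[names(densities)] <- densities
  structure(list(volume_fractions = volume_fractions, densities = dens),
            class = "shinemap_mixture")
}

.mass_attenuation <- function(material, energy) {
  tab <- .read_table("mass_attenuation.txt",
                     c("material", "energy_keV", "mu_over_rho"))
  if (inherits(material, "shinemap_mixture")) {
    vf <- material$volume_fractions
    rho <- material$densities
    w <- vf * rho
    w <- w / sum(w)                      # mass fractions
    out <- 0
    for (comp in names(vf)) {
      sub <- tab[tab$material == comp, ]
      out <- out + w[[comp]] * .loglog_interp(energy, sub$energy_keV, sub$mu_over_rho)
    }
    return(out)
  }
  sub <- tab[tab$material == material, ]
  if (nrow(sub) == 0L) .stop_cls("shinemap_range_error", "unknown material: ", material)
  .loglog_interp(energy, sub$energy_keV, sub$mu_over_rho)
}

#' Linear attenuation coefficient
#'
#' \eqn{\mu = (\mu/\rho)(E) \cdot \rho}, log-log interpolated in energy,
#' returned in 1/m.  \code{material} is \code{"air"}, \code{"soil"},
#' \code{"concrete"} or a \code{\link{mixture}}; for a mixture the mass
#' attenuation coefficient is the mass-fraction-weighted combination of the
#' component tables.
#'
#' @param material Material identifier or \code{\link{mixture}} object.
#' @param energy_keV Photon energy in keV (vectorised).
#' @param density Bulk density in g/cm3; defaults to the packaged density
#'   of the material (for a mixture, the volume-weighted component density).
#' @return Linear attenuation coefficient(s) in 1/m.
#' @export
linear_attenuation <- function(material, energy_keV, density = NULL) {
  if (is.null(density)) {
    density <- if (inherits(material, "shinemap_mixture"))
      sum(material$volume_fractions * material$densities)
    else .default_density[[material]]
  }
  stopifnot(density >= 0)
  mu_rho <- .mass_attenuation(material, energy_keV)   # cm2/g (validates range)
  mu_rho * density * 100                              # 1/cm -> 1/m
}

#' Berger buildup factor
#'
#' \eqn{B(\mu r) = 1 + a\,\mu r\,e^{b \mu r}} with (a, b) log-log
#' interpolated in energy from the packaged coefficient table.
#'
#' @param material Material identifier ("air", "soil", "concrete").
#' @param energy_keV Photon energy in keV.
#' @param mu_r Optical depth (dimensionless), vectorised, must be >= 0.
#' @return Buildup factor(s) >= 1.
#' @export
buildup <- function(material, energy_keV, mu_r) {
  if (any(mu_r < 0))
    .stop_cls("shinemap_domain_error", "mu_r must be non-negative")
  ab <- .berger_ab(material, energy_keV)
  1 + ab$a * mu_r * exp(ab$b * mu_r)
}

.berger_ab <- function(material, energy_keV) {
  tab <- .read_table("berger_buildup.txt", c("material", "energy_keV", "a", "b"))
  sub <- tab[tab$material == material, ]
  if (nrow(sub) == 0L) .stop_cls("shinemap_range_error", "unknown material: ", material)
  list(a = .loglog_interp(energy_keV, sub$energy_keV, sub$a),
       b = .loglog_interp(energy_keV, sub$energy_keV, sub$b))
}

.normalize_quantity <- function(quantity) {
  q <- tolower(gsub("[^a-z0-9]", "", tolower(quantity)))
  if (q %in% c("h10", "hstar10", "ambientdoseequivalent")) return("hstar10")
  if (q %in% c("kerma", "airkerma", "airkermafreeinair")) return("kerma")
  .stop_cls("shinemap_format_error", "unknown dose quantity: ", quantity)
}

#' Fluence-to-dose conversion coefficient
#'
#' Log-log interpolated ICRP-74-style conversion coefficient: ambient dose
#' equivalent H*(10) per fluence (pSv cm2) or air kerma free-in-air per
#' fluence (pGy cm2).
#'
#' @param quantity \code{"H*(10)"} or \code{"air kerma"}.
#' @param energy_keV Photon energy in keV (vectorised).
#' @return Conversion coefficient(s).
#' @export
fluence_to_dose <- function(quantity, energy_keV) {
  q <- .normalize_quantity(quantity)
  tab <- .read_table("fluence_to_dose.txt", c("quantity", "energy_keV", "coeff"))
  sub <- tab[tab$quantity == q, ]
  .loglog_interp(energy_keV, sub$energy_keV, sub$coeff)
}
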