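# Photon interaction data for the materials the engine transports through.
#
# Mass attenuation (mu/rho) and mass energy-absorption (muen/rho)
# coefficients, cm^2/g, tabulated at the standard grid energies and
# interpolated log-log in between.  Values follow the standard NIST-style
# compilations for elemental aluminium and the ICRU-44 body tissues; they are
# embedded so the package needs no external data.  All analytic cross-checks
# in the test-suite use these same tables, so internal consistency -- not
# agreement with any particular external compilation -- is what the package
# guarantees.

.MAT_ENERGIES <- c(10, 15, 20, 30, 40, 50, 60, 80, 100, 150) # keV

.MAT_TABLES <- list(
  aluminium = list(
    mu   = c(26.23, 7.955, 3.441, 1.128, 0.5685, 0.3681, 0.2778, 0.2018, 0.1704, 0.1378),
    muen = c(25.43, 7.487, 3.094, 0.8778, 0.3601, 0.1840, 0.1099, 0.05511, 0.03794, 0.02827),
    za = 0.48181, density = 2.699),
  air = list(
    mu   = c(5.120, 1.614, 0.7779, 0.3538, 0.2485, 0.2080, 0.1875, 0.1662, 0.1541, 0.1356),
    muen = c(4.742, 1.334, 0.5389, 0.1537, 0.06833, 0.04098, 0.03041, 0.02407, 0.02325, 0.02496),
    za = 0.49919, density = 0.0012041),
  water = list(
    mu   = c(5.329, 1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059, 0.1837, 0.1707, 0.1505),
    muen = c(4.944, 1.374, 0.5503, 0.1557, 0.06947, 0.04223, 0.03190, 0.02597, 0.02546, 0.02764),
    za = 0.55509, density = 1.000),
  soft_tissue = list(
    mu   = c(5.271, 1.658, 0.8090, 0.3780, 0.2685, 0.2262, 0.2048, 0.1823, 0.1693, 0.1492),
    muen = c(4.900, 1.363, 0.5462, 0.1550, 0.06944, 0.04233, 0.03203, 0.02608, 0.02555, 0.02771),
    za = 0.54996, density = 1.060),
  adipose = list(
    mu   = c(3.268, 1.085, 0.5737, 0.3051, 0.2352, 0.2067, 0.1915, 0.1737, 0.1620, 0.1434),
    muen = c(2.958, 0.8362, 0.3396, 0.1021, 0.05352, 0.03621, 0.02931, 0.02542, 0.02539, 0.02788),
    za = 0.55579, density = 0.950),
  lung = list(
    mu   = c(5.351, 1.683, 0.8198, 0.3818, 0.2708, 0.2278, 0.2061, 0.1834, 0.1702, 0.1500),
    muen = c(4.977, 1.385, 0.5549, 0.1572, 0.07028, 0.04276, 0.03229, 0.02623, 0.02567, 0.02782),
    za = 0.55048, density = 0.260),
  bone = list(
    mu   = c(28.51, 9.032, 4.001, 1.331, 0.6655, 0.4242, 0.3148, 0.2229, 0.1855, 0.1480),
    muen = c(26.80, 8.388, 3.601, 1.070, 0.4507, 0.2336, 0.1400, 0.06896, 0.04585, 0.03183),
    za = 0.51478, density = 1.920)
)

#' Materials known to the transport engine
#'
#' @return Character vector of material names accepted by [mu_rho()] and
#'   [muen_rho()].
#' @export
material_names <- function() names(.MAT_TABLES)

.lookup_material <- function(material) {
  tab <- .MAT_TABLES[[material]]
  if (is.null(tab)) {
    stop("unknown material '", material, "'; see material_names()", call. = FALSE)
  }
  tab
}

.loglog_interp <- function(x_tab, y_tab, x) {
  x <- pmin(pmax(x, x_tab[1]), x_tab[length(x_tab)])
  exp(stats::approx(log(x_tab), log(y_tab), xout = log(x), rule = 2)$y)
}

#' Mass attenuation coefficient
#'
#' Total mass attenuation coefficient mu/rho of a material, log-log
#' interpolated from the embedded tables. Energies outside the tabulated
#' range (10--150 keV) are clamped to the nearest endpoint.
#'
#' @param material One of [material_names()].
#' @param energy_kev Photon energy (keV), vectorized.
#' @return mu/rho in cm^2/g.
#' @export
mu_rho <- function(material, energy_kev) {
  stopifnot(all(energy_kev > 0))
  tab <- .lookup_material(material)
  .loglog_interp(.MAT_ENERGIES, tab$mu, energy_kev)
}

#' Mass energy-absorption coefficient
#'
#' @inheritParams mu_rho
#' @return muen/rho in cm^2/g.
#' @export
muen_rho <- function(material, energy_kev) {
  stopifnot(all(energy_kev > 0))
  tab <- .lookup_material(material)
  .loglog_interp(.MAT_ENERGIES, tab$muen, energy_kev)
}

#' Nominal density of a material
#' @inheritParams mu_rho
#' @return Density in g/cm^3.
#' @export
material_density <- function(material) .lookup_material(material)$density

# Klein-Nishina total cross-section per electron (cm^2) at energy keV.
.kn_total <- function(energy_kev) {
  k <- energy_kev / 510.998950
  re2 <- (2.8179403262e-13)^2
  term1 <- (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k)
  term2 <- log(1 + 2 * k) / (2 * k)
  term3 <- (1 + 3 * k) / (1 + 2 * k)^2
  2 * pi * re2 * (term1 + term2 - term3)
}

# Interaction partition used by the Monte Carlo kernel, on a 1-keV grid.
# Incoherent scatter is modelled free-electron Klein-Nishina on the
# material's electrons-per-gram; the remainder of the tabulated total is
# split 85% photoelectric / 15% coherent (a documented approximation --
# coherent scatter changes direction only and photoelectric deposits
# locally, so the split has second-order influence on dose).
.interaction_partition <- function(material, energies = 5:150) {
  tab <- .lookup_material(material)
  avogadro <- 6.02214076e23
  tot <- .loglog_interp(.MAT_ENERGIES, tab$mu, energies)
  incoh <- pmin(tab$za * avogadro * .kn_total(energies), tot)
  rest <- pmax(tot - incoh, 0)
  list(energies = energies, total = tot, incoherent = incoh,
       photoelectric = 0.85 * rest, coherent = 0.15 * rest)
}
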