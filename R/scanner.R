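# Virtual CT source: equivalent energy spectrum matched to a measured first
# HVL, bowtie filter profile fitted from lateral free-in-air dose readings,
# geometry presets, and air-kerma calibration.

.AL_DENSITY <- 2.699 # g/cm^3

#' Scanner geometry
#'
#' @param focus_isocenter_mm Focus-to-isocenter distance (mm).
#' @param fan_half_angle_rad Half fan angle (rad).
#' @param collimation_mm Total beam collimation at isocenter (mm).
#' @param rotation_time_s Rotation time (s).
#' @param pitch Helical pitch (dimensionless).
#' @return Object of class `scanner_geometry`.
#' @export
scanner_geometry <- function(focus_isocenter_mm, fan_half_angle_rad,
                             collimation_mm, rotation_time_s = 0.5,
                             pitch = 1.0) {
  vals <- c(focus_isocenter_mm, fan_half_angle_rad, collimation_mm,
            rotation_time_s, pitch)
  if (any(vals <= 0)) stop("all geometry parameters must be positive", call. = FALSE)
  structure(list(focus_isocenter_mm = focus_isocenter_mm,
                 fan_half_angle_rad = fan_half_angle_rad,
                 collimation_mm = collimation_mm,
                 rotation_time_s = rotation_time_s, pitch = pitch),
            class = "scanner_geometry")
}

#' Built-in scanner presets
#'
#' Two presets mirroring typical wide-bore PET/CT geometries: `"siemens"`
#' (focus-isocenter 595 mm, full fan angle 0.7955 rad, 19.2 mm collimation,
#' pitch 0.7) and `"ge"` (541 mm, 0.8658 rad, 40 mm, pitch 0.984). The
#' vendor fan-angle figures are full-fan values; half-fan is stored.
#'
#' @param name `"siemens"` or `"ge"`.
#' @return A [scanner_geometry()].
#' @export
scanner_preset <- function(name = c("siemens", "ge")) {
  name <- match.arg(name)
  switch(name,
    siemens = scanner_geometry(595, 0.7955 / 2, 19.2, 0.5, 0.7),
    ge      = scanner_geometry(541, 0.8658 / 2, 40.0, 0.5, 0.984))
}

#' Construct a normalized spectrum
#'
#' @param energy_kev Bin midpoints (keV).
#' @param fluence Non-negative relative fluence; renormalized to unit sum.
#' @param kvp Tube voltage (kV); fluence must vanish above it.
#' @return Object of class `ct_spectrum`.
#' @export
ct_spectrum <- function(energy_kev, fluence, kvp) {
  if (length(energy_kev) != length(fluence)) stop("length mismatch", call. = FALSE)
  if (any(fluence < 0)) stop("fluence must be non-negative", call. = FALSE)
  if (sum(fluence) <= 0) stop("spectrum has zero total fluence", call. = FALSE)
  if (any(fluence[energy_kev > kvp] > 0)) {
    stop("fluence above kVp must be zero", call. = FALSE)
  }
  structure(list(energy_kev = energy_kev, fluence = fluence / sum(fluence),
                 kvp = kvp),
            class = "ct_spectrum")
}

#' @export
print.ct_spectrum <- function(x, ...) {
  mean_e <- sum(x$energy_kev * x$fluence)
  cat(sprintf("<ct_spectrum> %d kVp, %d bins, mean energy %.1f keV\n",
              x$kvp, length(x$energy_kev), mean_e))
  invisible(x)
}

# Parametric base tube spectrum: Kramers bremsstrahlung N(E) ~ (kvp - E)/E
# behind inherent filtration, plus tungsten K lines when kvp exceeds the
# K edge (69.5 keV). 1-keV bins over [10, kvp].
.base_spectrum <- function(kvp, inherent_al_mm = 2.5) {
  e <- seq(10, kvp, by = 1)
  n <- pmax(kvp - e, 0) / e
  n <- n * exp(-mu_rho("aluminium", e) * .AL_DENSITY * inherent_al_mm / 10)
  if (kvp > 69.5) {
    lines <- c(`58` = 0.030, `59` = 0.055, `67` = 0.015) # Ka2, Ka1, Kb
    tot <- sum(n)
    for (le in names(lines)) {
      idx <- which(e == as.numeric(le))
      n[idx] <- n[idx] + lines[[le]] * tot
    }
  }
  ct_spectrum(e, n, kvp)
}

# Air-kerma weight per unit fluence at each bin: E * (muen/rho)_air.
.kerma_weight <- function(energy_kev) energy_kev * muen_rho("air", energy_kev)

# Spectrum-weighted aluminium transmission of the air-kerma signal.
.al_transmission <- function(spectrum, t_mm) {
  w <- spectrum$fluence * .kerma_weight(spectrum$energy_kev)
  atten <- exp(-mu_rho("aluminium", spectrum$energy_kev) * .AL_DENSITY * t_mm / 10)
  sum(w * atten) / sum(w)
}

#' First half-value layer of a spectrum
#'
#' Aluminium thickness halving the air-kerma-weighted transmitted
#' intensity, solved by bracketing and bisection to 1e-4 mm. (HVL here is
#' defined on air kerma, not fluence.)
#'
#' @param spectrum A [ct_spectrum()].
#' @return First HVL in mm Al.
#' @export
compute_first_hvl <- function(spectrum) {
  stopifnot(inherits(spectrum, "ct_spectrum"))
  f <- function(t) .al_transmission(spectrum, t) - 0.5
  lo <- 0; hi <- 1
  while (f(hi) > 0 && hi < 200) hi <- hi * 2
  if (f(hi) > 0) stop("HVL exceeds 200 mm Al; degenerate spectrum", call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = 1e-5)$root
}

#' Equivalent spectrum matched to a measured first HVL
#'
#' Starts from the package's parametric tube spectrum at the given kVp and
#' searches the added aluminium filtration (0--20 mm) until the computed
#' first HVL matches the measured one within 0.01 mm Al, then returns the
#' filtered, renormalized spectrum (with the added filtration recorded as
#' attribute `added_al_mm`).
#'
#' @param kvp Tube voltage (kV).
#' @param target_hvl_mm_al Measured first HVL (mm Al).
#' @param max_added_al_mm Filtration search bound (mm Al).
#' @return A [ct_spectrum()].
#' @export
generate_equivalent_spectrum <- function(kvp, target_hvl_mm_al,
                                         max_added_al_mm = 20) {
  base <- .base_spectrum(kvp)
  filter_al <- function(t_mm) {
    fl <- base$fluence *
      exp(-mu_rho("aluminium", base$energy_kev) * .AL_DENSITY * t_mm / 10)
    ct_spectrum(base$energy_kev, fl, kvp)
  }
  h0 <- compute_first_hvl(base)
  hmax <- compute_first_hvl(filter_al(max_added_al_mm))
  if (target_hvl_mm_al < h0 - 0.01 || target_hvl_mm_al > hmax + 0.01) {
    stop(sprintf(
      "target HVL %.3f mm Al unattainable; achievable range [%.3f, %.3f] mm Al",
      target_hvl_mm_al, h0, hmax), call. = FALSE)
  }
  if (abs(target_hvl_mm_al - h0) <= 0.01) {
    out <- base
    attr(out, "added_al_mm") <- 0
    return(out)
  }
  g <- function(t) compute_first_hvl(filter_al(t)) - target_hvl_mm_al
  t_star <- stats::uniroot(g, c(0, max_added_al_mm), tol = 1e-4)$root
  out <- filter_al(t_star)
  attr(out, "added_al_mm") <- t_star
  out
}

#' Bowtie profile
#'
#' @param fan_angle_rad Sample angles (rad), symmetric about 0.
#' @param equivalent_al_mm Equivalent added aluminium thickness per angle
#'   (mm), >= 0, minimum at angle 0.
#' @return Object of class `bowtie_profile`; use
#'   [bowtie_thickness()] to evaluate it.
#' @export
bowtie_profile <- function(fan_angle_rad, equivalent_al_mm) {
  stopifnot(length(fan_angle_rad) == length(equivalent_al_mm))
  if (any(equivalent_al_mm < 0)) stop("thickness must be >= 0", call. = FALSE)
  o <- order(fan_angle_rad)
  structure(list(fan_angle_rad = fan_angle_rad[o],
                 equivalent_al_mm = equivalent_al_mm[o]),
            class = "bowtie_profile")
}

#' Evaluate a bowtie profile
#' @param profile A [bowtie_profile()].
#' @param angle_rad Fan angles (rad), vectorized; evaluated on |angle|.
#' @return Equivalent Al thickness (mm).
#' @export
bowtie_thickness <- function(profile, angle_rad) {
  stopifnot(inherits(profile, "bowtie_profile"))
  stats::approx(profile$fan_angle_rad, profile$equivalent_al_mm,
                xout = abs(angle_rad), rule = 2)$y
}

#' Fit a bowtie profile from lateral free-in-air dose readings
#'
#' Converts each lateral position at isocenter to a fan angle via
#' `atan(pos / focus_isocenter)`, then solves per angle for the equivalent
#' aluminium thickness whose spectrum-weighted air-kerma transmission
#' equals the measured reading relative to the central one. Readings above
#' the central value would need negative thickness; they are clamped to 0
#' with a warning. The fitted profile is defined on |angle| (symmetric).
#'
#' @param lateral_positions_mm Positions at isocenter (mm), must include 0.
#' @param measured_doses Relative free-in-air readings (> 0).
#' @param geometry A [scanner_geometry()].
#' @param spectrum A [ct_spectrum()].
#' @return A [bowtie_profile()].
#' @export
fit_bowtie_profile <- function(lateral_positions_mm, measured_doses,
                               geometry, spectrum) {
  stopifnot(inherits(geometry, "scanner_geometry"),
            inherits(spectrum, "ct_spectrum"))
  if (length(lateral_positions_mm) < 3 || !any(lateral_positions_mm == 0)) {
    stop("need >= 3 positions including 0", call. = FALSE)
  }
  if (any(measured_doses <= 0)) stop("doses must be positive", call. = FALSE)
  centre <- measured_doses[which(lateral_positions_mm == 0)[1]]
  ratio <- measured_doses / centre
  theta <- atan(abs(lateral_positions_mm) / geometry$focus_isocenter_mm)
  t_of_ratio <- function(r) {
    if (r >= 1) {
      if (r > 1 + 1e-12) {
        warning("off-axis reading above centre; thickness clamped at 0",
                call. = FALSE)
      }
      return(0)
    }
    f <- function(t) .al_transmission(spectrum, t) - r
    hi <- 1
    while (f(hi) > 0 && hi < 500) hi <- hi * 2
    stats::uniroot(f, c(0, hi), tol = 1e-5)$root
  }
  t_mm <- vapply(ratio, t_of_ratio, numeric(1))
  agg <- stats::aggregate(t_mm, list(theta = theta), mean)
  bowtie_profile(agg$theta, agg$x)
}

#' Air-kerma calibration
#'
#' Converts a measured free-in-air air kerma per mAs at the isocenter into
#' the photons-per-mAs normalization of the Monte Carlo source. The
#' per-source-photon kerma along the central (unfiltered) ray is computed
#' in closed form for the free-in-air case: photons are emitted uniformly
#' over the fan x cone angular window, so the fluence per photon at the
#' isocenter is `1 / (4 * u * v * d^2)` with `u`, `v` the half fan and
#' half cone angles and `d` the focus-isocenter distance.
#'
#' @param spectrum A [ct_spectrum()].
#' @param geometry A [scanner_geometry()].
#' @param measured_kerma_per_mAs Measured free-in-air kerma (mGy/mAs), > 0.
#' @return Object of class `kerma_calibration` with
#'   `air_kerma_per_mAs_at_isocenter` and `photons_per_mAs`.
#' @export
calibrate_air_kerma <- function(spectrum, geometry, measured_kerma_per_mAs) {
  stopifnot(inherits(spectrum, "ct_spectrum"),
            inherits(geometry, "scanner_geometry"))
  if (!is.numeric(measured_kerma_per_mAs) || measured_kerma_per_mAs <= 0) {
    stop("measured kerma per mAs must be positive", call. = FALSE)
  }
  k <- kerma_per_photon(spectrum, geometry)
  if (k <= 0) stop("simulated per-photon kerma is zero; check configuration",
                   call. = FALSE)
  structure(list(air_kerma_per_mAs_at_isocenter = measured_kerma_per_mAs,
                 photons_per_mAs = measured_kerma_per_mAs / k),
            class = "kerma_calibration")
}

#' Free-in-air kerma per source photon at the isocenter
#'
#' Closed form used by [calibrate_air_kerma()] and by the transport
#' engine's absolute normalization: `sum_E w_E * E * (muen/rho)_air(E) *
#' Phi` with `Phi = 1/(4 u v d^2)` the per-photon fluence at isocenter.
#'
#' @inheritParams calibrate_air_kerma
#' @return Kerma in mGy per source photon.
#' @export
kerma_per_photon <- function(spectrum, geometry) {
  u <- geometry$fan_half_angle_rad
  v <- atan(geometry$collimation_mm / 2 / geometry$focus_isocenter_mm)
  d_cm <- geometry$focus_isocenter_mm / 10
  phi <- 1 / (4 * u * v * d_cm^2)             # photons / cm^2 per photon
  e_j <- spectrum$energy_kev * 1.602176634e-16
  k_gy <- sum(spectrum$fluence * e_j * muen_rho("air", spectrum$energy_kev) * 1000) * phi
  k_gy * 1000                                  # mGy
}

#' Assemble a scanner model bundle
#'
#' @param geometry A [scanner_geometry()].
#' @param spectrum A [ct_spectrum()].
#' @param bowtie A [bowtie_profile()] (flat profile if omitted).
#' @param calibration A [calibrate_air_kerma()] result; if omitted, a
#'   nominal free-in-air kerma of 0.16 mGy/mAs at isocenter is assumed.
#' @return Object of class `scanner_model`.
#' @export
scanner_model <- function(geometry, spectrum, bowtie = NULL,
                          calibration = NULL) {
  stopifnot(inherits(geometry, "scanner_geometry"),
            inherits(spectrum, "ct_spectrum"))
  if (is.null(bowtie)) bowtie <- bowtie_profile(c(0, 1), c(0, 0))
  if (is.null(calibration)) {
    calibration <- calibrate_air_kerma(spectrum, geometry, 0.16)
  }
  structure(list(geometry = geometry, spectrum = spectrum, bowtie = bowtie,
                 calibration = calibration),
            class = "scanner_model")
}

#' Build a scanner model from characterization data
#'
#' Convenience wrapper chaining [generate_equivalent_spectrum()],
#' [fit_bowtie_profile()] and [calibrate_air_kerma()] from a plain
#' characterization list (such as one read from a JSON config):
#' `kvp`, `hvl_mm_al`, optional `bowtie_measurements` (two-column matrix of
#' position mm and relative dose), `kerma_per_mAs`.
#'
#' @param geometry A [scanner_geometry()] or preset name.
#' @param characterization Named list as above.
#' @return A [scanner_model()].
#' @export
build_scanner_model <- function(geometry, characterization) {
  if (is.character(geometry)) geometry <- scanner_preset(geometry)
  ch <- characterization
  spec <- generate_equivalent_spectrum(ch$kvp, ch$hvl_mm_al)
  bow <- NULL
  if (!is.null(ch$bowtie_measurements)) {
    bm <- ch$bowtie_measurements
    bow <- fit_bowtie_profile(bm[, 1], bm[, 2], geometry, spec)
  }
  cal <- calibrate_air_kerma(spec, geometry, ch$kerma_per_mAs %||% 0.16)
  scanner_model(geometry, spec, bow, cal)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
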