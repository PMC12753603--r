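test_that("scanner presets carry the advertised geometry", {
  s <- scanner_preset("siemens")
  g <- scanner_preset("ge")
  expect_equal(s$focus_isocenter_mm, 595)
  expect_equal(s$fan_half_angle_rad, 0.7955 / 2)
  expect_equal(s$collimation_mm, 19.2)
  expect_equal(s$pitch, 0.7)
  expect_equal(g$focus_isocenter_mm, 541)
  expect_equal(g$collimation_mm, 40)
  expect_equal(g$pitch, 0.984)
  expect_error(scanner_geometry(-1, 0.4, 20), "positive")
})

test_that("spectra are normalized, bounded by kVp, with K lines only above the edge", {
  s120 <- ctdosim:::.base_spectrum(120)
  expect_equal(sum(s120$fluence), 1, tolerance = 1e-12)
  expect_true(all(s120$energy_kev <= 120))
  expect_true(any(s120$fluence[s120$energy_kev %in% c(58, 59, 67)] >
                    2 * stats::median(s120$fluence)))
  s60 <- ctdosim:::.base_spectrum(60)
  expect_true(all(s60$energy_kev <= 60))
})

test_that("HVL increases with added filtration", {
  s <- ctdosim:::.base_spectrum(120)
  h <- vapply(c(0, 2, 5), function(t) {
    w <- s$fluence * exp(-mu_rho("aluminium", s$energy_kev) *
                           material_density("aluminium") * t / 10)
    compute_first_hvl(ct_spectrum(s$energy_kev, w, 120))
  }, numeric(1))
  expect_true(all(diff(h) > 0))
})

test_that("equivalent-spectrum generation records added filtration and flags impossible targets", {
  sp <- generate_equivalent_spectrum(120, 8.5)
  expect_gt(attr(sp, "added_al_mm"), 0)
  expect_equal(compute_first_hvl(sp), 8.5, tolerance = 0.01)
  expect_error(generate_equivalent_spectrum(120, 2), "achievable")
  expect_error(generate_equivalent_spectrum(120, 14), "achievable")
})

test_that("bowtie profiles are symmetric and clamp invalid readings", {
  ang <- seq(0, 0.4, length.out = 9)
  bt <- bowtie_profile(ang, 10 * (ang / 0.4)^2)
  expect_equal(bowtie_thickness(bt, -0.3), bowtie_thickness(bt, 0.3))
  expect_equal(bowtie_thickness(bt, 0), 0)
  geom <- scanner_preset("siemens")
  sp <- generate_equivalent_spectrum(120, 7.8)
  w <- capture_warnings(
    fit_bowtie_profile(c(-100, 0, 100), c(1.2, 1.0, 1.2), geom, sp))
  expect_true(any(grepl("clamped", w)))
  expect_error(fit_bowtie_profile(c(1, 2), c(1, 1), geom, sp), "positions")
})

test_that("property: bowtie fit inverts synthetic transmission readings", {
  geom <- scanner_preset("siemens")
  sp <- generate_equivalent_spectrum(120, 7.8)
  set.seed(17)
  for (k in 1:5) {
    tmax <- runif(1, 4, 20)
    ang <- seq(0, geom$fan_half_angle_rad, length.out = 15)
    true <- bowtie_profile(ang, tmax * (ang / max(ang))^runif(1, 1, 3))
    pos <- tan(seq(-max(ang) * 0.9, max(ang) * 0.9, length.out = 17)) *
      geom$focus_isocenter_mm
    pos[which.min(abs(pos))] <- 0
    th <- atan(abs(pos) / geom$focus_isocenter_mm)
    tr <- vapply(th, function(a)
      ctdosim:::.al_transmission(sp, bowtie_thickness(true, a)), numeric(1))
    fit <- fit_bowtie_profile(pos, tr, geom, sp)
    expect_lt(max(abs(bowtie_thickness(fit, th) - bowtie_thickness(true, th))),
              0.01)
  }
})

test_that("air-kerma calibration inverts the per-photon kerma", {
  geom <- scanner_preset("siemens")
  sp <- generate_equivalent_spectrum(120, 7.8)
  cal <- calibrate_air_kerma(sp, geom, measured_kerma_per_mAs = 0.16)
  expect_equal(cal$photons_per_mAs * kerma_per_photon(sp, geom), 0.16,
               tolerance = 1e-10)
})

test_that("build_scanner_model assembles a usable model from a characterization", {
  m <- quick_scanner()
  expect_s3_class(m, "scanner_model")
  expect_equal(compute_first_hvl(m$spectrum), 7.8, tolerance = 0.01)
  expect_true(m$calibration$photons_per_mAs > 0)
})
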