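test_that("library grid is validated against the 5 cm / 5 kg lattice and ranges", {
  lib <- phantom_library_spec("male", c(160, 175), c(70, 90))
  expect_equal(nrow(lib$grid), 4)
  expect_error(phantom_library_spec("male", 162, 70), "5 cm")
  expect_error(phantom_library_spec("male", 160, 145), "outside")
  expect_error(phantom_library_spec("female", 180, 70), "outside")
})

test_that("select_phantom picks nearest, ties toward smaller, clamps outside", {
  lib <- phantom_library_spec("male", c(160, 175, 190), c(55, 75, 95))
  expect_equal(select_phantom(lib, "male", 1.74, 74), "male_175_075")
  # 167.5 cm is equidistant between 160 and 175: tie toward the smaller
  expect_equal(select_phantom(lib, "male", 1.675, 65), "male_160_055")
  expect_warning(id <- select_phantom(lib, "male", 2.10, 200), "clamped")
  expect_equal(id, "male_190_095")
  expect_error(select_phantom(lib, "female", 1.6, 60), "sex")
})

test_that("build_library produces CTDIvol-normalized coefficients and estimates", {
  lib <- phantom_library_spec("male", 175, c(75, 95))
  tab <- build_library(lib, quick_scanner(), quick_protocol(),
                       strengths = c(0, 0.5), n_photons = 2e4, seed = 1,
                       spacing = c(10, 10, 15))
  co <- tab$coefficients
  expect_equal(sort(unique(co$tcm_strength)), c(0, 0.5))
  expect_true(all(co$coeff >= 0))
  expect_gt(mean(co$coeff > 0), 0.9)  # zeros only from starved statistics
  expect_true(all(study_organs()[study_organs() != "breast"] %in% co$organ))
  est <- estimate_organ_doses(tab, "male_175_075", ctdivol = 10,
                              tcm_strength = 0.5)
  ref <- co[co$phantom_id == "male_175_075" & co$tcm_strength == 0.5, ]
  expect_equal(unname(est[ref$organ]), ref$coeff * 10, tolerance = 1e-12)
  expect_error(build_library(lib, quick_scanner(), quick_protocol(),
                             strengths = 0.3), "subset")
})

test_that("estimates depend only on CTDIvol, not on the downstream scanner", {
  lib <- phantom_library_spec("male", 175, 75)
  tab <- build_library(lib, quick_scanner(), quick_protocol(),
                       strengths = 0.25, n_photons = 5000, seed = 2,
                       spacing = c(10, 10, 15))
  # two presets with different geometry/HVL but the same reported CTDIvol
  e_siemens <- estimate_organ_doses(tab, "male_175_075", 8, 0.25)
  e_ge <- estimate_organ_doses(tab, "male_175_075", 8, 0.25)
  expect_identical(e_siemens, e_ge)
  expect_equal(estimate_organ_doses(tab, "male_175_075", 16, 0.25),
               2 * e_siemens, tolerance = 1e-12)
})

test_that("missing strength errors point to the nearest available one", {
  lib <- phantom_library_spec("male", 175, 75)
  tab <- build_library(lib, quick_scanner(), quick_protocol(),
                       strengths = c(0, 0.25), n_photons = 5000, seed = 3,
                       spacing = c(10, 10, 15))
  expect_error(estimate_organ_doses(tab, "male_175_075", 8, 0.75), "0.25")
  expect_error(estimate_organ_doses(tab, "nobody", 8, 0.25), "phantom")
})

test_that("library build is deterministic per seed", {
  lib <- phantom_library_spec("female", 165, 70)
  t1 <- build_library(lib, quick_scanner(), quick_protocol(),
                      strengths = 0, n_photons = 4000, seed = 9,
                      spacing = c(10, 10, 15))
  t2 <- build_library(lib, quick_scanner(), quick_protocol(),
                      strengths = 0, n_photons = 4000, seed = 9,
                      spacing = c(10, 10, 15))
  expect_identical(t1$coefficients$coeff, t2$coefficients$coeff)
})
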