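test_that("HU to material conversion follows the piecewise curve", {
  v <- voxel_volume(array(c(-1000, -950, -600, -100, 30, 500, 1200),
                          c(7, 1, 1)), spacing = c(1, 1, 1))
  mm <- hu_to_material(v)
  got <- mm$materials[mm$material_index[, 1, 1]]
  expect_equal(got, c("air", "air", "lung", "adipose", "water", "bone", "bone"))
  expect_true(all(diff(mm$density[, 1, 1]) > 0))
  expect_equal(mm$density[1, 1, 1], 0.0012, tolerance = 1e-6)
  expect_equal(mm$density[5, 1, 1], 1.0, tolerance = 0.05)
})

test_that("dose_grid validates its input", {
  expect_error(dose_grid(matrix(0, 2, 2), c(1, 1, 1)), "3-D")
  expect_error(dose_grid(array(-1, c(2, 2, 2)), c(1, 1, 1)), "non-negative")
})

test_that("simulation rejects tiny photon counts and restores the RNG", {
  mats <- water_box(nx = 10, ny = 10, nz = 4)
  sc <- scan_definition(quick_protocol(), NULL, quick_scanner())
  expect_error(simulate_helical_scan(mats, sc, n_photons = 10), ">= 1000")
  set.seed(77)
  before <- .Random.seed
  invisible(simulate_helical_scan(mats, sc, n_photons = 2000, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("fixed seed gives bit-identical dose grids", {
  mats <- water_box(nx = 20, ny = 20, nz = 6)
  sc <- scan_definition(quick_protocol(), NULL, quick_scanner())
  d1 <- simulate_helical_scan(mats, sc, n_photons = 5000, seed = 42)
  d2 <- simulate_helical_scan(mats, sc, n_photons = 5000, seed = 42)
  d3 <- simulate_helical_scan(mats, sc, n_photons = 5000, seed = 43)
  expect_identical(d1$dose, d2$dose)
  expect_false(identical(d1$dose, d3$dose))
})

test_that("dose scales exactly linearly with tube current", {
  mats <- water_box(nx = 20, ny = 20, nz = 6)
  scan1 <- scan_definition(quick_protocol(reference_mA = 100), NULL,
                           quick_scanner())
  scan2 <- scan_definition(quick_protocol(reference_mA = 200), NULL,
                           quick_scanner())
  d1 <- simulate_helical_scan(mats, scan1, n_photons = 5000, seed = 7)
  d2 <- simulate_helical_scan(mats, scan2, n_photons = 5000, seed = 7)
  nz <- d1$dose > 0
  expect_true(all(abs(d2$dose[nz] / d1$dose[nz] - 2) < 1e-12))
})

test_that("energy ledger balances exactly", {
  mats <- water_box(nx = 20, ny = 20, nz = 6)
  sc <- scan_definition(quick_protocol(), NULL, quick_scanner())
  d <- simulate_helical_scan(mats, sc, n_photons = 20000, seed = 11)
  led <- d$energy_ledger
  bal <- led[["emitted"]] -
    (led[["deposited"]] + led[["escaped"]] + led[["discarded"]])
  expect_lt(abs(bal) / led[["emitted"]], 1e-12)
})

test_that("TCM weighting shifts dose along z in proportion to current", {
  mats <- water_box(nx = 20, ny = 20, nz = 10)
  prot <- quick_protocol()
  cur <- c(rep(200, 5), rep(100, 5))
  tcm <- tcm_profile(cur)
  d <- simulate_helical_scan(mats, scan_definition(prot, tcm, quick_scanner()),
                             n_photons = 4e5, seed = 5)
  mid <- function(sl) mean(d$dose[8:13, 8:13, sl])
  ratio <- mean(vapply(2:4, mid, numeric(1))) /
    mean(vapply(7:9, mid, numeric(1)))
  expect_gt(ratio, 1.5)  # 2:1 current modulation visible in central dose
  expect_lt(ratio, 2.5)
})

test_that("property: dose noise shrinks roughly as 1/sqrt(n)", {
  mats <- water_box(nx = 16, ny = 16, nz = 4)
  sc <- scan_definition(quick_protocol(), NULL, quick_scanner())
  spread <- function(n, seeds) {
    v <- vapply(seeds, function(s) {
      d <- simulate_helical_scan(mats, sc, n_photons = n, seed = s)
      mean(d$dose[6:11, 6:11, 2:3])
    }, numeric(1))
    stats::sd(v)
  }
  s_small <- spread(2000, 1:8)
  s_big <- spread(32000, 1:8)
  expect_lt(s_big, s_small / 2)  # expected factor 4, allow wide noise margin
})

test_that("CTDIvol estimator warns below the supported photon count", {
  expect_warning(
    estimate_ctdivol(quick_scanner(), quick_protocol(), n_photons = 5e4,
                     seed = 1),
    "photon")
})

test_that("axial and stationary modes run and deposit dose", {
  mats <- water_box(nx = 20, ny = 20, nz = 6)
  sc <- scan_definition(quick_protocol(), NULL, quick_scanner())
  for (m in c("axial", "stationary")) {
    d <- simulate_helical_scan(mats, sc, n_photons = 3000, seed = 2, mode = m)
    expect_gt(sum(d$dose), 0)
  }
})
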