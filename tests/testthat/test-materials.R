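test_that("material tables cover the required media", {
  nm <- material_names()
  expect_true(all(c("air", "water", "soft_tissue", "adipose", "lung",
                    "bone", "aluminium") %in% nm))
  for (m in nm) {
    expect_gt(material_density(m), 0)
    expect_true(all(mu_rho(m, c(10, 30, 60, 100, 150)) > 0))
    expect_true(all(muen_rho(m, c(10, 30, 60, 100, 150)) > 0))
  }
})

test_that("attenuation coefficients decrease over the diagnostic range", {
  e <- seq(15, 140, 5)
  for (m in c("water", "aluminium", "bone", "soft_tissue")) {
    expect_true(all(diff(mu_rho(m, e)) < 0), info = m)
  }
})

test_that("mass energy-absorption never exceeds mass attenuation", {
  e <- seq(10, 150, 2.5)
  for (m in material_names()) {
    expect_true(all(muen_rho(m, e) <= mu_rho(m, e) * (1 + 1e-12)), info = m)
  }
})

test_that("unknown materials are rejected; out-of-range energies clamp", {
  expect_error(mu_rho("plutonium", 60), "material")
  expect_equal(mu_rho("water", 5), mu_rho("water", 10))     # clamped low
  expect_equal(muen_rho("water", 200), muen_rho("water", 150))  # clamped high
  expect_error(mu_rho("water", -10))
})

test_that("property: interaction partition sums to the total cross-section", {
  set.seed(31)
  for (m in c("water", "bone", "lung", "adipose", "air", "soft_tissue")) {
    p <- ctdosim:::.interaction_partition(m)
    recon <- p$photoelectric + p$incoherent + p$coherent
    expect_lt(max(abs(recon - p$total) / p$total), 1e-12)
    expect_true(all(p$photoelectric >= 0) && all(p$incoherent >= 0) &&
                  all(p$coherent >= 0))
  }
})

test_that("log-log interpolation reproduces the table nodes exactly", {
  e_nodes <- ctdosim:::.MAT_ENERGIES
  tab <- ctdosim:::.MAT_TABLES[["water"]]$mu
  expect_equal(mu_rho("water", e_nodes), tab, tolerance = 1e-12)
})
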