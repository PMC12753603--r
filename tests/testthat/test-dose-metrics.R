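test_that("body contour fills internal air so gas counts toward the ROI", {
  v <- make_cylinder_phantom(120, 24, material_hu = 0, spacing = c(2, 2, 6))
  hole <- v
  d <- dim(v)
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  hole$values[(cx - 3):(cx + 3), (cy - 3):(cy + 3), ] <- -1000
  c_full <- extract_body_contour(v, warn = FALSE)
  c_hole <- extract_body_contour(hole, warn = FALSE)
  expect_equal(c_hole$area_roi, c_full$area_roi)          # hole filled
  expect_lt(c_hole$mean_hu[1], c_full$mean_hu[1])         # air lowers mean HU
})

test_that("all-air slices are excluded with a warning", {
  v <- make_cylinder_phantom(100, 18, material_hu = 0, spacing = c(2, 2, 6))
  v$values[, , 1] <- -1000
  expect_warning(ct <- extract_body_contour(v), "excluded")
  expect_false(ct$analyzed[1])
  expect_true(all(ct$analyzed[-1]))
  expect_true(is.na(water_equivalent_diameter(ct)[1]))
  expect_error(water_equivalent_diameter(ct, slice = 1), "not analyzed")
})

test_that("D_W of a -500 HU cylinder matches the analytic value", {
  v <- make_cylinder_phantom(200, 18, material_hu = -500, spacing = c(1, 1, 6))
  ct <- extract_body_contour(v, threshold_hu = -600, warn = FALSE)
  dw <- water_equivalent_diameter(ct, slice = 2)
  expect_equal(dw, 200 * sqrt(0.5), tolerance = 1e-3)
})

test_that("ssde validates inputs and reports both bases", {
  expect_error(ssde(100, ctdivol = -1), "positive")
  expect_error(ssde(100, 5, coefficients = c(1, NA)), "coefficients")
  expect_error(ssde(100, 5, coefficients = c(-1, 0.1)), "a > 0")
  expect_error(ssde(-5, 5), "non-negative")
  s <- ssde(c(100, NA, 120), 10, phantom_basis = "16cm")
  expect_equal(s$phantom_diameter_basis, "16cm")
  expect_equal(s$mean_dw, 110)
})

test_that("organ_dose rejects mismatched grids and empty masks", {
  v <- voxel_volume(array(0, c(4, 4, 2)), spacing = c(2, 2, 4))
  m <- array(FALSE, c(4, 4, 2)); m[1:2, 1:2, 1] <- TRUE
  om <- organ_mask("x", m, v)
  bad <- dose_grid(array(1, c(3, 3, 2)), c(2, 2, 4))
  expect_error(organ_dose(bad, om), "differ")
})

test_that("property: fractional-area dose is translation invariant", {
  set.seed(23)
  d <- c(12, 12, 6)
  v <- voxel_volume(array(0, d), spacing = c(2, 2, 4))
  dose_arr <- array(runif(prod(d)), d)
  m <- array(FALSE, d); m[3:5, 3:6, 2:4] <- TRUE
  shift <- array(FALSE, d); shift[6:8, 5:8, 3:5] <- TRUE
  dose <- dose_grid(dose_arr, c(2, 2, 4))
  d1 <- organ_dose(dose, organ_mask("a", m, v))$dose_mGy
  expect_equal(d1, mean(dose_arr[m]), tolerance = 1e-12)
  d2 <- organ_dose(dose, organ_mask("a", shift, v))$dose_mGy
  expect_equal(d2, mean(dose_arr[shift]), tolerance = 1e-12)
})

test_that("normalize_to_ctdivol divides and validates", {
  v <- voxel_volume(array(0, c(3, 3, 2)), spacing = c(2, 2, 4))
  m <- array(TRUE, c(3, 3, 2))
  r <- organ_dose(dose_grid(array(6, c(3, 3, 2)), c(2, 2, 4)),
                  organ_mask("x", m, v))
  r <- normalize_to_ctdivol(r, 3)
  expect_equal(r$normalized_dose, 2)
  expect_error(normalize_to_ctdivol(r, 0), "positive")
})
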