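test_that("patient_record derives BMI and category", {
  r <- patient_record("male", 1.76, 79)
  expect_equal(r$bmi, 79 / 1.76^2, tolerance = 1e-12)
  expect_equal(as.character(r$bmi_category), "overweight")
  expect_error(patient_record("male", -1, 70), "positive")
  expect_error(patient_record("other", 1.7, 70))
})

test_that("cylinder phantom has the requested geometry", {
  v <- make_cylinder_phantom(160, 60, material_hu = 0, spacing = c(2, 2, 6))
  inside <- v$values[, , 1] > -1000
  area <- sum(inside) * 4
  expect_equal(area, pi * 80^2, tolerance = 0.02)
  expect_equal(dim(v)[3], 10)
  expect_true(all(v$values %in% c(-1000, 0)))
})

test_that("sub-voxel cylinder collapses to a single-voxel column by policy", {
  v <- make_cylinder_phantom(1, 30, material_hu = 100, spacing = c(4, 4, 6))
  per_slice <- apply(v$values > -1000, 3, sum)
  expect_true(all(per_slice == 1))
})

test_that("adult phantom is deterministic per seed and restores the RNG", {
  rec <- patient_record("male", 1.76, 79)
  set.seed(123)
  before <- .Random.seed
  p1 <- make_adult_phantom(rec, seed = 5)
  expect_identical(.Random.seed, before)
  p2 <- make_adult_phantom(rec, seed = 5)
  p3 <- make_adult_phantom(rec, seed = 6)
  expect_identical(p1$volume$values, p2$volume$values)
  expect_false(identical(p1$volume$values, p3$volume$values))
})

test_that("adult phantom contains the expected organs and tissue HUs", {
  for (sex in c("male", "female")) {
    rec <- patient_record(sex, if (sex == "male") 1.76 else 1.63, 70)
    ph <- make_adult_phantom(rec, seed = 2)
    expected <- setdiff(study_organs(), if (sex == "male") "breast")
    expect_true(all(expected %in% names(ph$masks)), info = sex)
    hu <- ph$volume$values
    expect_true(any(hu == -1000) && any(hu < -500 & hu > -900) &&
                  any(hu > 300))  # air, lung, bone present
  }
})

test_that("property: heavier subjects produce larger mid-torso sections", {
  areas <- vapply(c(55, 85, 115), function(w) {
    ph <- make_adult_phantom(patient_record("male", 1.75, w), seed = 3)
    mid <- dim(ph$volume)[3] %/% 2
    sum(ph$volume$values[, , mid] > -400) * prod(ph$volume$spacing[1:2])
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("TCM profile renormalizes to the reference current", {
  ph <- make_adult_phantom(patient_record("male", 1.76, 79), seed = 4)
  for (s in c(0, 0.25, 0.5, 1)) {
    tcm <- generate_tcm_profile(ph$volume, s, reference_mA = 120)
    expect_equal(mean(tcm$tube_current_per_slice), 120, tolerance = 1e-9)
    expect_true(all(tcm$tube_current_per_slice > 0))
  }
  flat <- generate_tcm_profile(ph$volume, 0, reference_mA = 100)
  expect_true(all(flat$tube_current_per_slice == 100))
})

test_that("property: TCM current ratios follow the attenuation power law", {
  ph <- make_adult_phantom(patient_record("male", 1.80, 90), seed = 8)
  ct <- extract_body_contour(ph$volume, warn = FALSE)
  w <- ct$water_equiv_area
  set.seed(9)
  for (s in runif(4)) {
    tcm <- generate_tcm_profile(ph$volume, s, reference_mA = 100)
    i <- tcm$tube_current_per_slice
    expect_equal(i[3] / i[10], (w[3] / w[10])^s, tolerance = 1e-8)
  }
})

test_that("organ_mask computes per-slice contour areas", {
  v <- voxel_volume(array(0, c(4, 4, 3)), spacing = c(2, 3, 5))
  m <- array(FALSE, c(4, 4, 3)); m[1:2, 1, 1] <- TRUE; m[1, 1, 3] <- TRUE
  om <- organ_mask("x", m, v)
  expect_equal(om$per_slice_area, c(12, 0, 6))
  expect_error(organ_mask("x", array(FALSE, c(4, 4, 3)), v), "at least one")
  expect_error(organ_mask("x", array(TRUE, c(2, 2, 2)), v), "shape")
})
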