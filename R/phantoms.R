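# Synthetic voxel phantoms: containers plus the stylized-anatomy generators
# that stand in for patient CT data.

.HU_AIR  <- -1000
.HU_LUNG <- -700
.HU_FAT  <- -90
.HU_SOFT <- 40
.HU_BONE <- 700

.STUDY_ORGANS <- c("thyroid", "oesophagus", "lungs", "heart", "breast",
                   "liver", "kidneys")

#' Tissue Hounsfield-unit defaults for the stylized phantoms
#'
#' @return Named numeric vector (air, lung, fat, soft, bone) in HU. Pass a
#'   modified copy to [make_adult_phantom()] to override.
#' @export
tissue_hu_defaults <- function() {
  c(air = .HU_AIR, lung = .HU_LUNG, fat = .HU_FAT, soft = .HU_SOFT,
    bone = .HU_BONE)
}

#' Study organ list
#' @return Character vector of the seven organs carried through the study.
#' @export
study_organs <- function() .STUDY_ORGANS

#' Construct a voxel volume
#'
#' A 3-D grid of CT numbers (HU) with voxel spacing and origin. The slice
#' (longitudinal) axis is always the third array axis.
#'
#' @param values 3-D numeric array of HU in [-1024, 3071].
#' @param spacing Numeric length-3, voxel spacing (x, y, z) in mm, all > 0.
#' @param origin Numeric length-3, position of the first voxel centre in mm.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("spacing must be three positive numbers (mm)", call. = FALSE)
  }
  if (any(values < -1024) || any(values > 3071)) {
    stop("HU values must lie within [-1024, 3071]", call. = FALSE)
  }
  structure(list(values = values, spacing = spacing, origin = origin,
                 slice_axis = 3L),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  HU range [%.0f, %.0f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

#' Construct an organ mask
#'
#' Boolean grid congruent with its volume, plus the derived per-slice
#' contour areas A_i = (voxel count in slice i) x (in-plane voxel area).
#'
#' @param organ_name Organ label.
#' @param mask 3-D logical array, same shape as the volume.
#' @param volume The [voxel_volume()] the mask belongs to.
#' @return An object of class `organ_mask`.
#' @export
organ_mask <- function(organ_name, mask, volume) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (!identical(dim(mask), dim(volume$values))) {
    stop("mask shape must equal volume shape", call. = FALSE)
  }
  if (!any(mask)) stop("mask must contain at least one voxel", call. = FALSE)
  area_px <- volume$spacing[1] * volume$spacing[2]
  per_slice_area <- apply(mask, 3, sum) * area_px
  structure(list(organ_name = organ_name, mask = (mask != 0),
                 per_slice_area = per_slice_area,
                 spacing = volume$spacing),
            class = "organ_mask")
}

#' @export
print.organ_mask <- function(x, ...) {
  cat(sprintf("<organ_mask> %s: %d voxels over %d slices\n", x$organ_name,
              sum(x$mask), sum(x$per_slice_area > 0)))
  invisible(x)
}

#' Construct a patient record
#'
#' Anthropometrics with derived BMI and BMI category (boundaries at
#' 18.5, 25.0 and 30.0 kg/m^2; left-closed intervals).
#'
#' @param sex `"male"` or `"female"`.
#' @param height_m Height in metres.
#' @param weight_kg Weight in kilograms.
#' @param age_years Age (informational).
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(sex, height_m, weight_kg, age_years = 60) {
  sex <- match.arg(sex, c("male", "female"))
  if (height_m <= 0 || weight_kg <= 0) {
    stop("height and weight must be positive", call. = FALSE)
  }
  bmi <- weight_kg / height_m^2
  structure(list(sex = sex, age = age_years, height = height_m,
                 weight = weight_kg, bmi = bmi,
                 bmi_category = bmi_category(weight_kg, height_m)),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s, %.2f m, %.0f kg (BMI %.1f, %s)\n",
              x$sex, x$height, x$weight, x$bmi,
              as.character(x$bmi_category)))
  invisible(x)
}

#' Cylinder phantom (analytic test fixture)
#'
#' A homogeneous cylinder of the given material HU surrounded by air
#' (-1000 HU), axis along the slice axis.
#'
#' @param diameter_mm,length_mm Cylinder dimensions (mm), > 0.
#' @param material_hu HU inside the cylinder.
#' @param spacing Voxel spacing (x, y, z) in mm.
#' @param margin_mm Air margin added around the cylinder.
#' @return A [voxel_volume()]. A diameter below one voxel yields a
#'   single-voxel column (the voxel containing the axis), by policy.
#' @export
make_cylinder_phantom <- function(diameter_mm, length_mm, material_hu = 0,
                                  spacing = c(4, 4, 6), margin_mm = 20) {
  if (diameter_mm <= 0 || length_mm <= 0) {
    stop("diameter and length must be positive", call. = FALSE)
  }
  r <- diameter_mm / 2
  nx <- max(3L, ceiling((diameter_mm + 2 * margin_mm) / spacing[1]))
  ny <- max(3L, ceiling((diameter_mm + 2 * margin_mm) / spacing[2]))
  nz <- max(1L, round(length_mm / spacing[3]))
  cx <- (nx - 1) / 2 * spacing[1]
  cy <- (ny - 1) / 2 * spacing[2]
  x <- (seq_len(nx) - 1) * spacing[1] - cx
  y <- (seq_len(ny) - 1) * spacing[2] - cy
  inside <- outer(x^2, y^2, `+`) <= r^2
  if (!any(inside)) inside[which.min(abs(x)), which.min(abs(y))] <- TRUE
  vals <- array(.HU_AIR, dim = c(nx, ny, nz))
  vals[rep(inside, nz)] <- material_hu
  voxel_volume(vals, spacing, origin = c(-cx, -cy, 0))
}

# Relative cross-section profile of the stylized torso along z (0 = neck,
# 1 = mid-thigh): narrow neck, broad shoulders/chest, waist, hips, thighs.
.torso_profile <- function(zfrac) {
  knots <- c(0.00, 0.04, 0.10, 0.30, 0.50, 0.65, 0.82, 1.00)
  vals  <- c(0.30, 0.55, 1.12, 1.08, 0.95, 1.12, 0.95, 0.72)
  stats::approx(knots, vals, xout = zfrac, rule = 2)$y
}

.ellipsoid_mask <- function(xg, yg, zg, centre, semi) {
  ((xg - centre[1]) / semi[1])^2 + ((yg - centre[2]) / semi[2])^2 +
    ((zg - centre[3]) / semi[3])^2 <= 1
}

#' Stylized adult phantom with organ masks
#'
#' Generates an elliptical-torso body from neck to mid-thigh with lung,
#' soft-tissue, subcutaneous-fat and bone (spine) compartments, and organ
#' masks for the seven study organs at anatomically ordered longitudinal
#' positions (thyroid most cranial, kidneys most caudal). Torso
#' cross-section scales with weight/height, so BMI drives the
#' water-equivalent diameter monotonically. Deterministic for a fixed
#' (record, seed); the seed jitters organ positions and sizes slightly.
#'
#' @param record A [patient_record()]; height in [1.40, 2.00] m, weight in
#'   [35, 150] kg.
#' @param seed Integer seed for the anatomical jitter.
#' @param spacing Voxel spacing (x, y, z) in mm.
#' @param hu Named tissue-HU vector, see [tissue_hu_defaults()].
#' @return List with elements `volume` (a [voxel_volume()]) and `masks`
#'   (named list of [organ_mask()]; no breast mask for males).
#' @export
make_adult_phantom <- function(record, seed = 1L, spacing = c(4, 4, 6),
                               hu = tissue_hu_defaults()) {
  stopifnot(inherits(record, "patient_record"))
  if (record$height < 1.40 || record$height > 2.00) {
    stop("height must lie within [1.40, 2.00] m", call. = FALSE)
  }
  if (record$weight < 35 || record$weight > 150) {
    stop("weight must lie within [35, 150] kg", call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  torso_len <- 0.52 * record$height * 1000          # mm, neck to mid-thigh
  body_vol  <- record$weight / 1.05 * 1e6           # mm^3 at ~1.05 g/cm^3
  mean_area <- 0.75 * body_vol / torso_len          # mm^2 torso share
  nz <- max(10L, round(torso_len / spacing[3]))
  zfrac <- (seq_len(nz) - 0.5) / nz
  area_z <- mean_area * .torso_profile(zfrac)
  area_z <- area_z * mean_area / mean(area_z)       # preserve mean area
  aspect <- 0.72                                    # AP / lateral
  a_z <- sqrt(area_z / (pi * aspect))               # lateral semi-axis mm
  b_z <- aspect * a_z

  margin <- 16
  nx <- ceiling((2 * max(a_z) + 2 * margin) / spacing[1])
  ny <- ceiling((2 * max(b_z) + 2 * margin) / spacing[2])
  x <- (seq_len(nx) - 1) * spacing[1]; x <- x - mean(x)
  y <- (seq_len(ny) - 1) * spacing[2]; y <- y - mean(y)
  z <- (seq_len(nz) - 0.5) * spacing[3]
  xg <- array(rep(x, times = ny * nz), dim = c(nx, ny, nz))
  yg <- array(rep(rep(y, each = nx), times = nz), dim = c(nx, ny, nz))
  zg <- array(rep(z, each = nx * ny), dim = c(nx, ny, nz))
  az <- array(rep(a_z, each = nx * ny), dim = c(nx, ny, nz))
  bz <- array(rep(b_z, each = nx * ny), dim = c(nx, ny, nz))

  rho2 <- (xg / az)^2 + (yg / bz)^2
  body <- rho2 <= 1
  vals <- array(hu[["air"]], dim = c(nx, ny, nz))
  # subcutaneous fat ring: thickness grows with BMI
  t_fat <- min(60, max(3, (record$bmi - 19) * 2.2))  # mm
  inner <- (xg / pmax(az - t_fat, 5))^2 + (yg / pmax(bz - t_fat, 5))^2 <= 1
  vals[body]  <- hu[["fat"]]
  vals[inner] <- hu[["soft"]]

  zmm <- function(f) f * torso_len
  jit <- function(sd_mm) stats::rnorm(1, 0, sd_mm)

  # lungs: two ellipsoids in the chest
  lungs_c <- zmm(0.22) + jit(4)
  lung_hw <- 0.42 * mean(a_z[zfrac > 0.1 & zfrac < 0.35])
  lung_l <- .ellipsoid_mask(xg, yg, zg, c(-0.45 * mean(a_z) + jit(2), -0.05 * mean(b_z), lungs_c),
                            c(lung_hw, 0.60 * mean(b_z), zmm(0.15)))
  lung_r <- .ellipsoid_mask(xg, yg, zg, c(0.45 * mean(a_z) + jit(2), -0.05 * mean(b_z), lungs_c),
                            c(lung_hw, 0.60 * mean(b_z), zmm(0.15)))
  lungs <- (lung_l | lung_r) & inner
  vals[lungs] <- hu[["lung"]]

  # spine: posterior bone column over the full torso
  spine <- (xg^2 + (yg - (-0.62) * bz)^2) <= 14^2
  spine <- spine & inner
  vals[spine] <- hu[["bone"]]

  masks <- list()
  add_organ <- function(name, m) {
    m <- m & inner & !spine
    if (any(m)) masks[[name]] <<- m
    m
  }
  iz_neck <- max(1L, round(0.035 * nz))
  thy <- add_organ("thyroid",
    .ellipsoid_mask(xg, yg, zg, c(jit(1), 0.30 * b_z[iz_neck], zmm(0.035)),
                    c(16, 10, 12)))
  oes <- add_organ("oesophagus",
    (xg - jit(1))^2 + (yg - (-0.30) * bz)^2 <= 7^2 &
      zg > zmm(0.02) & zg < zmm(0.45))
  add_organ("lungs", lungs)
  heart_semi <- c(0.30, 0.30, 0.09) * c(mean(a_z), mean(b_z), torso_len)
  hea <- add_organ("heart",
    .ellipsoid_mask(xg, yg, zg, c(-0.12 * mean(a_z) + jit(2), 0.12 * mean(b_z), zmm(0.28) + jit(3)),
                    heart_semi) & !lungs)
  if (record$sex == "female") {
    iz_chest <- max(1L, round(0.24 * nz))
    a_ch <- a_z[iz_chest]; b_ch <- b_z[iz_chest]
    br_l <- .ellipsoid_mask(xg, yg, zg, c(-0.42 * a_ch, 0.72 * b_ch, zmm(0.24)),
                            c(0.28 * a_ch, 0.35 * b_ch, zmm(0.07)))
    br_r <- .ellipsoid_mask(xg, yg, zg, c(0.42 * a_ch, 0.72 * b_ch, zmm(0.24)),
                            c(0.28 * a_ch, 0.35 * b_ch, zmm(0.07)))
    breast <- (br_l | br_r) & body
    if (any(breast)) {
      vals[breast & !inner] <- hu[["fat"]]
      masks[["breast"]] <- breast
    }
  }
  liv <- add_organ("liver",
    .ellipsoid_mask(xg, yg, zg, c(0.35 * mean(a_z) + jit(3), 0.05 * mean(b_z), zmm(0.43) + jit(4)),
                    c(0.42 * mean(a_z), 0.55 * mean(b_z), zmm(0.08))) & !lungs)
  kid_l <- .ellipsoid_mask(xg, yg, zg, c(-0.38 * mean(a_z) + jit(2), -0.35 * mean(b_z), zmm(0.54) + jit(3)),
                           c(0.14 * mean(a_z), 0.22 * mean(b_z), zmm(0.05)))
  kid_r <- .ellipsoid_mask(xg, yg, zg, c(0.38 * mean(a_z) + jit(2), -0.35 * mean(b_z), zmm(0.54) + jit(3)),
                           c(0.14 * mean(a_z), 0.22 * mean(b_z), zmm(0.05)))
  add_organ("kidneys", kid_l | kid_r)

  vol <- voxel_volume(vals, spacing, origin = c(min(x), min(y), spacing[3] / 2))
  masks <- lapply(names(masks), function(nm) organ_mask(nm, masks[[nm]], vol))
  names(masks) <- vapply(masks, function(m) m$organ_name, character(1))
  list(volume = vol, masks = masks, record = record, seed = seed)
}

#' Tube-current-modulation profile
#'
#' Emulates a generic longitudinal TCM model: the per-slice tube current
#' follows a power of the slice water-equivalent area,
#' `I_i = I_ref * (W_i / mean(W))^s`, renormalized so the scan-mean current
#' equals `reference_mA`. `s = 0` gives a constant (unmodulated) profile;
#' `s = 1` makes the current proportional to the slice's water-equivalent
#' attenuation area.
#'
#' @param volume A [voxel_volume()].
#' @param strength Modulation strength s in [0, 1].
#' @param reference_mA Scan-mean tube current (mA), > 0.
#' @return An object of class `tcm_profile` with fields
#'   `tube_current_per_slice`, `source`, `strength`.
#' @export
generate_tcm_profile <- function(volume, strength, reference_mA = 100) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (strength < 0 || strength > 1) stop("strength must lie in [0, 1]", call. = FALSE)
  if (reference_mA <= 0) stop("reference_mA must be positive", call. = FALSE)
  contour <- extract_body_contour(volume, warn = FALSE)
  w <- contour$water_equiv_area
  w[!contour$analyzed] <- NA
  if (all(is.na(w))) stop("volume has no body-bearing slices", call. = FALSE)
  w[is.na(w)] <- mean(w, na.rm = TRUE)
  cur <- reference_mA * (w / mean(w))^strength
  cur <- cur * reference_mA / mean(cur)
  tcm_profile(cur, source = "generated", strength = strength)
}

#' Construct a TCM profile from explicit per-slice currents
#'
#' @param tube_current_per_slice Positive mA values, one per slice.
#' @param source `"header_extracted"` or `"generated"`.
#' @param strength Optional generator strength in [0, 1].
#' @return An object of class `tcm_profile`.
#' @export
tcm_profile <- function(tube_current_per_slice, source = "header_extracted",
                        strength = NULL) {
  cur <- as.numeric(tube_current_per_slice)
  if (any(cur <= 0) || !length(cur)) stop("all currents must be positive", call. = FALSE)
  structure(list(tube_current_per_slice = cur,
                 source = match.arg(source, c("header_extracted", "generated")),
                 strength = strength),
            class = "tcm_profile")
}

#' @export
print.tcm_profile <- function(x, ...) {
  cat(sprintf("<tcm_profile> %d slices, mean %.1f mA (%s%s)\n",
              length(x$tube_current_per_slice),
              mean(x$tube_current_per_slice), x$source,
              if (!is.null(x$strength)) sprintf(", s=%.2f", x$strength) else ""))
  invisible(x)
}
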