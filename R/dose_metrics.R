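# Dose-summary formulas: body contour extraction, water-equivalent diameter
# D_W(z), size-specific dose estimate SSDE(z), fractional-area organ dose
# D_T, and CTDIvol normalization.

#' Extract the per-slice body contour of a volume
#'
#' Per slice: threshold at `threshold_hu`, keep the largest connected
#' component, fill internal holes (so lungs and bowel gas count toward the
#' imaged-body ROI, as in AAPM-220-style water-equivalent diameter
#' bookkeeping). Slices with no supra-threshold pixels are flagged as not
#' analyzed and excluded from scan means.
#'
#' @param volume A [voxel_volume()].
#' @param threshold_hu Body threshold, default -400 HU.
#' @param warn Warn about excluded (all-air) slices.
#' @return An object of class `body_contour` with logical `roi` (3-D),
#'   per-slice `area_roi` (mm^2), `mean_hu`, `water_equiv_area` (mm^2) and
#'   `analyzed` flags.
#' @export
extract_body_contour <- function(volume, threshold_hu = -400, warn = TRUE) {
  stopifnot(inherits(volume, "voxel_volume"))
  d <- dim(volume$values)
  roi <- array(FALSE, d)
  px_area <- volume$spacing[1] * volume$spacing[2]
  analyzed <- logical(d[3])
  for (i in seq_len(d[3])) {
    sl <- volume$values[, , i] > threshold_hu
    if (!any(sl)) next
    lab <- EBImage::bwlabel(sl)
    counts <- tabulate(lab[lab > 0])
    comp <- lab == which.max(counts)
    roi[, , i] <- EBImage::fillHull(comp) > 0
    analyzed[i] <- TRUE
  }
  if (warn && !all(analyzed)) {
    warning(sum(!analyzed), " slice(s) with no supra-threshold pixels excluded",
            call. = FALSE)
  }
  area <- apply(roi, 3, sum) * px_area
  mean_hu <- vapply(seq_len(d[3]), function(i) {
    if (!analyzed[i]) return(NA_real_)
    mean(volume$values[, , i][roi[, , i]])
  }, numeric(1))
  weq <- (mean_hu / 1000 + 1) * area
  weq <- pmax(weq, 0)
  structure(list(roi = roi, area_roi = area, mean_hu = mean_hu,
                 water_equiv_area = weq, analyzed = analyzed,
                 spacing = volume$spacing, threshold_hu = threshold_hu),
            class = "body_contour")
}

#' @export
print.body_contour <- function(x, ...) {
  cat(sprintf("<body_contour> %d/%d slices analyzed, mean ROI area %.0f mm^2\n",
              sum(x$analyzed), length(x$analyzed),
              mean(x$area_roi[x$analyzed])))
  invisible(x)
}

#' Water-equivalent diameter of a slice
#'
#' `D_W = 2 * sqrt((mean_HU/1000 + 1) * A_ROI / pi)` where `mean_HU` is the
#' average HU over the body ROI of the slice and `A_ROI` its area: the
#' bracket is the ROI's mean linear attenuation relative to water, so an
#' all-water ROI returns its own diameter and an all-air ROI returns zero.
#' A bracket that would be negative (mean HU below -1000) is clamped to
#' zero with a warning.
#'
#' @param contour A [extract_body_contour()] result.
#' @param slice Slice index; omit to get the whole per-slice vector.
#' @return D_W in mm (NA for non-analyzed slices when vectorized).
#' @export
water_equivalent_diameter <- function(contour, slice = NULL) {
  stopifnot(inherits(contour, "body_contour"))
  dw_all <- function(i) {
    if (!contour$analyzed[i]) return(NA_real_)
    if (contour$area_roi[i] <= 0) stop("zero ROI area", call. = FALSE)
    br <- contour$mean_hu[i] / 1000 + 1
    if (br < 0) {
      warning("negative water-equivalence bracket clamped to 0", call. = FALSE)
      br <- 0
    }
    2 * sqrt(br * contour$area_roi[i] / pi)
  }
  if (is.null(slice)) return(vapply(seq_along(contour$analyzed), dw_all, numeric(1)))
  if (!contour$analyzed[slice]) stop("slice was not analyzed (no body)", call. = FALSE)
  dw_all(slice)
}

#' Size-specific dose estimate along the scan
#'
#' `SSDE(z) = a * exp(-b * D_W(z)) * CTDIvol`, with `a`, `b` the exponential
#' conversion coefficients for the CTDI phantom basis used to report
#' CTDIvol (32 cm for body protocols). Shipping defaults follow the
#' published AAPM-220 32-cm body fit; supply your own pair to override.
#'
#' @param dw Per-slice water-equivalent diameters (mm); NAs (non-analyzed
#'   slices) are dropped from the means.
#' @param ctdivol CTDIvol of the acquisition (mGy), > 0.
#' @param coefficients Numeric `c(a, b)` with a > 0, b >= 0 (b in 1/mm).
#' @param phantom_basis `"32cm"` or `"16cm"` (label only).
#' @return Object of class `ssde_result`: `per_slice_dw`, `mean_dw`,
#'   `per_slice_ssde`, `mean_ssde`, `coefficients`, `ctdivol`,
#'   `phantom_diameter_basis`.
#' @export
ssde <- function(dw, ctdivol, coefficients = c(a = 3.704369, b = 0.003671937),
                 phantom_basis = c("32cm", "16cm")) {
  phantom_basis <- match.arg(phantom_basis)
  if (ctdivol <= 0) stop("ctdivol must be positive", call. = FALSE)
  if (length(coefficients) != 2 || is.null(coefficients) ||
      any(!is.finite(coefficients))) {
    stop("coefficients (a, b) are required", call. = FALSE)
  }
  a <- coefficients[[1]]; b <- coefficients[[2]]
  if (a <= 0 || b < 0) stop("require a > 0 and b >= 0", call. = FALSE)
  if (any(dw < 0, na.rm = TRUE)) stop("D_W must be non-negative", call. = FALSE)
  s <- a * exp(-b * dw) * ctdivol
  structure(list(per_slice_dw = dw, mean_dw = mean(dw, na.rm = TRUE),
                 per_slice_ssde = s, mean_ssde = mean(s, na.rm = TRUE),
                 coefficients = c(a = a, b = b), ctdivol = ctdivol,
                 phantom_diameter_basis = phantom_basis),
            class = "ssde_result")
}

#' @export
print.ssde_result <- function(x, ...) {
  cat(sprintf("<ssde_result> mean D_W %.1f mm, mean SSDE %.2f mGy (CTDIvol %.2f mGy, %s basis)\n",
              x$mean_dw, x$mean_ssde, x$ctdivol, x$phantom_diameter_basis))
  invisible(x)
}

#' Fractional-area organ dose
#'
#' `D_T = sum_i f_i * M_i` with `M_i` the mean dose over the organ contour
#' in slice i, `A_i` the contour area and `f_i = A_i / sum(A_i)`. With
#' uniform in-plane spacing this equals the plain mean over all mask
#' voxels; both are computed and asserted equal.
#'
#' @param dose A [dose_grid()] congruent with the mask's volume.
#' @param mask An [organ_mask()].
#' @return Object of class `organ_dose_result`: `organ_name`, `dose_mGy`,
#'   `per_slice` data frame (slice, area, mean dose, fraction), and
#'   `normalized_dose` (NA until [normalize_to_ctdivol()] is applied).
#' @export
organ_dose <- function(dose, mask) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "organ_mask"))
  if (!identical(dim(dose$dose), dim(mask$mask))) {
    stop("dose grid and mask shapes differ", call. = FALSE)
  }
  if (!any(mask$mask)) stop("empty organ mask", call. = FALSE)
  slices <- which(mask$per_slice_area > 0)
  m_i <- vapply(slices, function(i) mean(dose$dose[, , i][mask$mask[, , i]]),
                numeric(1))
  a_i <- mask$per_slice_area[slices]
  f_i <- a_i / sum(a_i)
  d_t <- sum(f_i * m_i)
  plain <- mean(dose$dose[mask$mask])
  stopifnot(abs(d_t - plain) <= 1e-9 * max(abs(plain), 1e-12))
  structure(list(organ_name = mask$organ_name, dose_mGy = d_t,
                 normalized_dose = NA_real_,
                 per_slice = data.frame(slice = slices, area_mm2 = a_i,
                                        mean_dose_mGy = m_i, fraction = f_i)),
            class = "organ_dose_result")
}

#' @export
print.organ_dose_result <- function(x, ...) {
  cat(sprintf("<organ_dose_result> %s: D_T = %.4g mGy over %d slices%s\n",
              x$organ_name, x$dose_mGy, nrow(x$per_slice),
              if (is.finite(x$normalized_dose))
                sprintf(" (%.3f mGy/mGy)", x$normalized_dose) else ""))
  invisible(x)
}

#' Normalize an organ dose to CTDIvol
#'
#' @param result An [organ_dose()] result.
#' @param ctdivol CTDIvol (mGy), > 0.
#' @return The result with `normalized_dose = D_T / CTDIvol` filled in.
#' @export
normalize_to_ctdivol <- function(result, ctdivol) {
  stopifnot(inherits(result, "organ_dose_result"))
  if (!is.numeric(ctdivol) || length(ctdivol) != 1 || ctdivol <= 0) {
    stop("ctdivol must be a positive number", call. = FALSE)
  }
  result$normalized_dose <- result$dose_mGy / ctdivol
  result
}
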