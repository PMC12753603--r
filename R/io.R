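# Format readers/writers, tube-current extraction, and the end-to-end
# mini-study driver chaining all stages.

#' Write a voxel volume (or mask) as NIfTI with a JSON sidecar
#'
#' @param volume A [voxel_volume()] or [organ_mask()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param sidecar Optional named list (patient record, protocol fields...)
#'   written next to the image as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, sidecar = NULL) {
  if (inherits(volume, "organ_mask")) {
    arr <- volume$mask * 1L
    spacing <- volume$spacing
    origin <- c(0, 0, 0)
  } else {
    stopifnot(inherits(volume, "voxel_volume"))
    arr <- volume$values
    spacing <- volume$spacing
    origin <- volume$origin
  }
  img <- RNifti::asNifti(arr, pixdim = spacing)
  RNifti::writeNifti(img, path)
  meta <- c(list(spacing = spacing, origin = origin), sidecar)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a voxel volume written by [write_volume()]
#'
#' @param path NIfTI path.
#' @return A [voxel_volume()]; the sidecar (if present) is attached as
#'   attribute `sidecar`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- c(0, 0, 0)
  sidecar <- NULL
  sc_path <- paste0(path, ".json")
  if (file.exists(sc_path)) {
    sidecar <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    if (!is.null(sidecar$origin)) origin <- as.numeric(sidecar$origin)
    if (!is.null(sidecar$spacing)) spacing <- as.numeric(sidecar$spacing)
  }
  vol <- voxel_volume(array(as.numeric(img), dim(img)), spacing, origin)
  attr(vol, "sidecar") <- sidecar
  vol
}

#' Extract per-slice tube currents from slice headers
#'
#' Reads a JSON sidecar of per-slice headers (a list of objects with a
#' slice position field and a tube-current field, mirroring the standard
#' X-Ray Tube Current image attribute), orders them by slice position --
#' not by file/listing order -- and fills isolated missing values by
#' nearest neighbour (ties toward the preceding slice) with a warning.
#'
#' @param headers Path to a JSON file, or a data frame / list with fields
#'   `slice_position` and `tube_current_mA`.
#' @return A [tcm_profile()] with `source = "header_extracted"`.
#' @export
extract_tube_currents <- function(headers) {
  if (is.character(headers)) {
    headers <- jsonlite::read_json(headers, simplifyVector = TRUE)
  }
  df <- as.data.frame(headers)
  if (!all(c("slice_position", "tube_current_mA") %in% names(df))) {
    stop("headers need slice_position and tube_current_mA fields", call. = FALSE)
  }
  df <- df[order(df$slice_position), ]
  cur <- as.numeric(df$tube_current_mA)
  if (all(is.na(cur))) stop("no tube-current attributes found", call. = FALSE)
  if (anyNA(cur)) {
    warning(sum(is.na(cur)), " missing tube-current value(s) filled by nearest neighbour",
            call. = FALSE)
    idx <- which(!is.na(cur))
    for (i in which(is.na(cur))) {
      j <- idx[which.min(abs(idx - i))]
      cur[i] <- cur[j]
    }
  }
  tcm_profile(cur, source = "header_extracted")
}

#' Default study configuration
#'
#' A scaled-down end-to-end study: cohort size, anthropometric ranges, the
#' exposure protocol, scanner characterization, phantom-library grid, TCM
#' strength and photon budget. Override any field by passing a
#' modified copy to [run_study()].
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed.
#' @param n_photons Photons per patient-specific simulation.
#' @param out_dir Output directory (NULL = no files written).
#' @return Named list (class `study_config`).
#' @export
study_config <- function(n_subjects = 6, seed = 1L, n_photons = 2e4,
                         out_dir = NULL) {
  structure(list(
    n_subjects = n_subjects,
    seed = seed,
    n_photons = n_photons,
    out_dir = out_dir,
    scanner_preset = "siemens",
    characterization = list(kvp = 120, hvl_mm_al = 7.8, kerma_per_mAs = 0.16),
    protocol = list(kvp = 120, pitch = 0.7, collimation_mm = 19.2,
                    rotation_time_s = 0.5, reference_mA = 100,
                    ctdivol = 8),
    estimate_ctdivol = FALSE,
    cohort = list(sex = "male", height_range_m = c(1.60, 1.90),
                  weight_range_kg = c(55, 115), tcm_strength = 0.25),
    library = list(heights_cm = c(160, 175, 190),
                   weights_kg = c(55, 75, 95, 115)),
    library_photons = 2e4,
    phantom_spacing = c(8, 8, 10),
    tcm_strength_estimate = 0.25
  ), class = "study_config")
}

#' Run the end-to-end mini-study
#'
#' Generates a synthetic cohort, simulates patient-specific doses with the
#' Monte Carlo engine, builds (or reuses) the phantom-library coefficient
#' table, estimates each subject's organ doses by phantom matching,
#' computes D_W / SSDE, and runs the agreement statistics. Fully
#' reproducible from (config, seed). When `config$out_dir` is set, the
#' per-subject dose table and the agreement report are written as CSV/JSON
#' with provenance (seed, photon counts).
#'
#' @param config A [study_config()].
#' @param library_table Optional pre-built [build_library()] table to reuse.
#' @return Object of class `agreement_report`: `doses` (long data frame:
#'   subject, organ, method, dose_mGy, normalized_dose, bmi_category,
#'   height, weight, mean_dw, mean_ssde), `percent_diff` summaries per
#'   organ, `icc` per organ, `deming` per organ, `ssde_fit` per organ, and
#'   `provenance`.
#' @export
run_study <- function(config = study_config(), library_table = NULL) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  scanner <- stage("scanner", build_scanner_model(config$scanner_preset,
                                                  config$characterization))
  p <- config$protocol
  protocol <- scan_protocol(kvp = p$kvp, pitch = p$pitch,
                            collimation_mm = p$collimation_mm,
                            rotation_time_s = p$rotation_time_s,
                            ctdivol = p$ctdivol,
                            reference_mA = p$reference_mA)
  if (is.null(protocol$ctdivol)) {
    if (!isTRUE(config$estimate_ctdivol)) {
      stop("[stage config] protocol CTDIvol missing and estimate_ctdivol disabled",
           call. = FALSE)
    }
    protocol$ctdivol <- as.numeric(stage("ctdivol",
      estimate_ctdivol(scanner, protocol, seed = config$seed)))
  }

  # cohort ------------------------------------------------------------------
  ch <- config$cohort
  set.seed(config$seed)
  heights <- stats::runif(config$n_subjects, ch$height_range_m[1],
                          ch$height_range_m[2])
  weights <- stats::runif(config$n_subjects, ch$weight_range_kg[1],
                          ch$weight_range_kg[2])
  records <- lapply(seq_len(config$n_subjects), function(i) {
    patient_record(ch$sex, heights[i], weights[i])
  })

  # phantom library ----------------------------------------------------------
  if (is.null(library_table)) {
    lib <- phantom_library_spec(ch$sex, config$library$heights_cm,
                                config$library$weights_kg)
    library_table <- stage("library", build_library(
      lib, scanner, protocol, strengths = config$tcm_strength_estimate,
      n_photons = config$library_photons, seed = config$seed,
      spacing = config$phantom_spacing))
  }
  lib <- library_table$library

  # patient-specific pathway -------------------------------------------------
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    rec <- records[[i]]
    ph <- stage("phantom", make_adult_phantom(rec, seed = config$seed + 100 + i,
                                              spacing = config$phantom_spacing))
    tcm <- generate_tcm_profile(ph$volume, strength = ch$tcm_strength,
                                reference_mA = protocol$reference_mA)
    mats <- hu_to_material(ph$volume)
    sc <- scan_definition(protocol, tcm, scanner)
    dg <- stage("mc", simulate_helical_scan(mats, sc,
                                            n_photons = config$n_photons,
                                            seed = config$seed + 500 + i))
    contour <- extract_body_contour(ph$volume, warn = FALSE)
    dw <- water_equivalent_diameter(contour)
    sres <- ssde(dw, protocol$ctdivol)
    pid <- select_phantom(lib, rec$sex, rec$height, rec$weight)
    est <- estimate_organ_doses(library_table, pid, protocol$ctdivol,
                                tcm_strength = config$tcm_strength_estimate)
    for (org in names(ph$masks)) {
      dt <- normalize_to_ctdivol(organ_dose(dg, ph$masks[[org]]),
                                 protocol$ctdivol)
      if (!org %in% names(est)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject = i, organ = org, sex = rec$sex, height_m = rec$height,
        weight_kg = rec$weight, bmi_category = as.character(rec$bmi_category),
        dose_mc_mGy = dt$dose_mGy, dose_lib_mGy = unname(est[org]),
        norm_mc = dt$normalized_dose,
        norm_lib = unname(est[org]) / protocol$ctdivol,
        mean_dw_mm = sres$mean_dw, mean_ssde_mGy = sres$mean_ssde,
        phantom_id = pid, stringsAsFactors = FALSE)
    }
  }
  doses <- do.call(rbind, rows)
  ok <- doses$dose_mc_mGy > 0 & doses$dose_lib_mGy > 0
  if (!all(ok)) {
    warning(sum(!ok),
            " organ dose(s) with a zero Monte Carlo or library estimate",
            " excluded from the agreement statistics; raise n_photons",
            call. = FALSE)
  }

  # agreement layer -----------------------------------------------------------
  per_organ <- split(doses[ok, ], doses$organ[ok])
  pd <- lapply(per_organ, function(d) {
    percent_difference_summary(percent_difference(d$dose_mc_mGy, d$dose_lib_mGy))
  })
  iccs <- lapply(per_organ, function(d) {
    if (nrow(d) >= 3) icc_absolute_agreement(d$dose_mc_mGy, d$dose_lib_mGy)
    else NULL
  })
  dem <- lapply(per_organ, function(d) {
    if (nrow(d) >= 3) deming_powerlaw(d$dose_mc_mGy, d$dose_lib_mGy) else NULL
  })
  sfit <- lapply(per_organ, function(d) {
    origin_regression(d$mean_ssde_mGy, d$dose_mc_mGy)
  })

  report <- structure(list(
    doses = doses, percent_diff = pd, icc = iccs, deming = dem,
    ssde_fit = sfit,
    provenance = list(seed = config$seed, n_photons = config$n_photons,
                      library_photons = config$library_photons,
                      ctdivol = protocol$ctdivol,
                      scanner_preset = config$scanner_preset,
                      tcm_strength_cohort = ch$tcm_strength,
                      tcm_strength_estimate = config$tcm_strength_estimate)),
    class = "agreement_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(doses, file.path(config$out_dir, "doses.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(provenance = report$provenance,
           percent_diff = pd,
           icc = lapply(iccs, function(z) if (is.null(z)) NULL else
             list(estimate = z$point_estimate, ci95 = unname(z$ci95))),
           deming = lapply(dem, function(z) if (is.null(z)) NULL else
             list(a = z$a, b = z$b)),
           ssde_fit = lapply(sfit, function(z)
             list(slope = z$slope, r_squared = z$r_squared))),
      file.path(config$out_dir, "agreement_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d subjects, %d organs\n",
              length(unique(x$doses$subject)), length(unique(x$doses$organ))))
  for (org in names(x$percent_diff)) {
    pdm <- x$percent_diff[[org]]
    icc <- x$icc[[org]]
    cat(sprintf("  %-11s mean diff %+6.1f%% [%+.1f, %+.1f]%s\n", org,
                pdm["mean"], pdm["min"], pdm["max"],
                if (!is.null(icc)) sprintf(", ICC %.3f", icc$point_estimate)
                else ""))
  }
  invisible(x)
}
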