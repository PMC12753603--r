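# Shared builders for the test suite. Kept deliberately small so unit
# tests stay fast; the acceptance tests build their own full-size objects.

quick_scanner <- function(kvp = 120, hvl = 7.8, kerma = 0.16) {
  build_scanner_model("siemens",
                      list(kvp = kvp, hvl_mm_al = hvl, kerma_per_mAs = kerma))
}

quick_protocol <- function(ctdivol = 8, pitch = 0.7, collimation = 19.2,
                           reference_mA = 100, ...) {
  scan_protocol(kvp = 120, pitch = pitch, collimation_mm = collimation,
                ctdivol = ctdivol, reference_mA = reference_mA, ...)
}

# A homogeneous water box as a material map (for transport physics tests).
water_box <- function(nx = 40, ny = 40, nz = 8, spacing = c(8, 8, 10),
                      hu = 0) {
  v <- voxel_volume(array(hu, c(nx, ny, nz)), spacing = spacing)
  hu_to_material(v)
}

# Small synthetic agreement data set with a known subject effect.
paired_doses <- function(n = 12, noise = 0.5, shift = 0, seed = 99) {
  set.seed(seed)
  subj <- runif(n, 5, 15)
  list(x = subj + rnorm(n, 0, noise), y = subj + shift + rnorm(n, 0, noise))
}
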