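---
title: "Methods: models, assumptions and numerical choices in ctdosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, assumptions and numerical choices in ctdosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ctdosim` is a self-contained study engine for comparing two routes to CT
organ dose: a *patient-specific* route (Monte Carlo transport on the
subject's own voxel model, with the subject's own tube-current modulation)
and a *computational-phantom* route (organ doses looked up from a
pre-computed library of CTDIvol-normalized coefficients on an
anthropometric grid). Everything needed to run such a comparison — phantom
generation, scanner characterization, transport, dose metrics, library
construction and agreement statistics — is implemented inside the package,
so results are reproducible from a seed with no external data.

This vignette documents the models, their assumptions, the main
parameters, and the limits of validity. All problem sizes used in examples
and tests (grid spacings, photon counts, cohort sizes) are the package's
own choices, selected to balance statistical precision against a
single-CPU time budget; they are not claims about any clinical system.

## 1. Synthetic anatomy

`make_adult_phantom()` builds a stylized adult torso on a voxel grid
(default spacing 4 x 4 x 6 mm; coarser grids are used in the examples for
speed):

* The torso is a stack of ellipses with a fixed lateral-to-AP aspect ratio
  of 0.72. The cross-section profile along the body axis (neck, shoulders,
  chest, waist, hips) is a smooth interpolation through fixed relative
  knots; absolute size is solved from the subject's height and weight
  (body volume = weight / 1.05 kg/L, torso taken as 75% of body volume
  over 52% of height).
* BMI controls a subcutaneous fat ring (thickness = clamp((BMI - 19) x
  2.2 mm, 3-60 mm)); a bone column of radius 14 mm models the spine;
  lungs, heart, liver, kidneys, oesophagus, thyroid and (female only)
  breast are placed as ellipsoids at anatomically motivated stations.
  Thyroid and breast use the *local* slice semi-axes at the neck and chest
  so they survive voxelization over the whole anthropometric range.
* A per-phantom seeded jitter varies organ positions and sizes slightly,
  so two subjects with identical height/weight are not voxel-identical.
  Generation saves and restores R's RNG state; phantoms are a pure
  function of `(record, seed, spacing)`.

Tissues are written as Hounsfield units (air -1000, lung -700, adipose
-90, soft tissue 40, bone 700). This is a *geometric* emulation: it
reproduces how attenuation, size and organ position drive dose, not
individual anatomy. There are no arms, no head below/above the torso, no
organ shape realism, and no contrast agents.

`generate_tcm_profile(volume, strength, reference_mA)` emulates
longitudinal tube-current modulation: slice current is proportional to
`(W(z) / mean(W))^strength`, where `W(z)` is the slice water-equivalent
area, renormalized so the scan mean equals the reference current.
`strength = 0` is a fixed current; `strength = 1` is full proportional
modulation. Angular (x-y) modulation is not modeled.

## 2. Scanner model

`scanner_geometry()` holds focus-isocenter distance, fan half-angle,
collimation, rotation time and pitch. Two presets mirror typical wide-bore
PET/CT geometries (`"siemens"`: 595 mm, 0.7955 rad full fan, 19.2 mm,
pitch 0.7; `"ge"`: 541 mm, 0.8658 rad full fan, 40 mm, pitch 0.984). The
vendor fan-angle figures are interpreted as *full* fan angles; presets
store the half-angle. If a site knows its half-angle convention differs,
pass a custom `scanner_geometry()`.

The energy spectrum is never taken from vendor data. Instead, the scanner
is characterized the way a physicist would:

* `generate_equivalent_spectrum(kvp, target_hvl)` starts from a Kramers
  bremsstrahlung shape behind 2.5 mm Al inherent filtration (plus tungsten
  K fluorescence lines at 58/59/67 keV when kVp exceeds the K edge) and
  solves for the added aluminium that reproduces the measured first
  half-value layer. HVL is defined on air-kerma-weighted transmission and
  solved by bisection to 1e-4 mm; the HVL-matched ("equivalent") spectrum
  reproduces beam penetration without claiming spectral truth.
* `fit_bowtie_profile()` converts lateral free-in-air readings at
  isocenter into an equivalent-aluminium bowtie thickness per fan angle by
  inverting the spectrum's transmission curve per reading.
* `calibrate_air_kerma()` anchors absolute output: the measured air kerma
  per mAs at isocenter fixes the number of emitted photons represented by
  one mAs.

`build_scanner_model()` bundles geometry + characterization into the
object the transport consumes.

## 3. Monte Carlo transport

`simulate_helical_scan()` runs a simplified photon Monte Carlo (compiled
kernel) over the material grid derived from HU
(`hu_to_material()`: air/lung/adipose/water-soft-tissue/bone with
piecewise-linear density):

* **Source**: photons start on the focal circle. Helical mode samples z
  uniformly over the scan range with gantry angle `2 pi dz / (pitch x
  collimation)`; axial mode is one uniform rotation; stationary mode is a
  fixed angle. Fan and cone angles are sampled uniformly; the bowtie is
  applied as an aluminium survival weight per fan angle, and per-slice TCM
  as a photon weight.
* **Transport**: Woodcock (delta) tracking against a per-energy majorant,
  which handles heterogeneous voxels without ray-voxel traversal.
* **Interactions**: incoherent (Compton) scattering with Klein-Nishina
  sampling (Kahn's method), energy deposited locally at each collision;
  photoelectric absorption deposits the full energy (kerma-style local
  deposition — secondary electrons are not transported, acceptable at CT
  energies where electron ranges are below the voxel size); coherent
  (Rayleigh) scattering redirects into a forward cone of at most 30 deg.
  Photons below 5 keV deposit locally. With `track_scatter = FALSE` every
  scattered photon (Compton *and* coherent) is discarded, which makes the
  mode a narrow-beam primary-attenuation experiment.
* **Cross-sections**: embedded mass-attenuation and mass
  energy-absorption tables (10-150 keV, log-log interpolated) for the
  seven materials. The interaction-type split uses the Klein-Nishina cross
  section for the incoherent part and divides the remainder 85% / 15%
  between photoelectric and coherent. That split is an approximation —
  the true partition is material- and energy-dependent — but every
  consistency check in the package is run against these same tables, so
  the engine is self-consistent by construction.
* **Normalization**: dose is absolute. Photon weight =
  `photons_per_mAs x total mAs / n_simulated`, with total mAs derived
  from scan length, pitch, collimation, rotation time and the TCM mean.
  The energy ledger (emitted = deposited + escaped + discarded) closes to
  machine precision and is returned with every run.

`estimate_ctdivol()` performs the standard axial measurement on a 32 cm
cylinder (100 mm line integrals at center and periphery, CTDIw = 1/3
center + 2/3 periphery, divided by pitch). The cylinder is modeled as
soft tissue (HU 130) rather than PMMA, since PMMA is not one of the
transported materials; CTDIvol is therefore used as a *consistent
internal normalization*, not as a calibrated PMMA value.

## 4. Dose metrics

* `extract_body_contour()`: per-slice threshold at -400 HU, largest
  connected component, holes filled (so lungs and bowel gas count toward
  the body ROI, as in AAPM-220-style bookkeeping).
* `water_equivalent_diameter()`: `D_W = 2 sqrt((mean_HU/1000 + 1) x
  A_ROI / pi)`. The `HU/1000` convention makes the bracket the ROI's mean
  linear attenuation relative to water, so a water cylinder returns its
  own diameter and air returns zero.
* `ssde()`: `SSDE(z) = a exp(-b D_W(z)) x CTDIvol` with the published
  32 cm body-phantom exponential coefficients (a = 3.704369,
  b = 0.003671937 per mm) as defaults; both are overridable.
* `organ_dose()`: fractional-area organ dose `D_T = sum_i f_i M_i` with
  per-slice area fractions `f_i`; with uniform in-plane spacing this
  equals the plain voxel mean, and the implementation asserts that
  identity on every call.

## 5. Phantom library and agreement layer

`build_library()` computes, for every phantom on a 5 cm / 5 kg grid (male
160-190 cm / 50-140 kg, female 150-175 cm / 40-135 kg) and every TCM
strength in {0, 0.25, 0.5, 0.75, 1}, the CTDIvol-normalized organ dose
coefficients. Coefficients depend only on tube voltage and TCM strength,
never on the scanner preset — the reference-scanner principle used by
phantom-based dosimetry tools — so two scanners reporting the same
CTDIvol yield identical library estimates. `select_phantom()` matches a
subject by nearest grid point (ties toward the smaller phantom; values
outside the grid are clamped with a warning), and
`estimate_organ_doses()` multiplies coefficients by the examination
CTDIvol.

The statistics module mirrors common method-comparison practice:
percentage differences (optionally BMI-stratified; categories are
left-closed at 18.5/25/30 kg/m^2), ICC(A,1) absolute agreement from
two-way mean squares with F-based 95% intervals, Deming power-law
regression in log-log space (default relative errors 10% for the
patient-specific method and 25% for the library method, with a 35%/15%
sensitivity refit), and through-origin regression of organ dose on SSDE.
`evaluate_tcm_sweep()` packages the strength-sweep experiment: percentage
differences are averaged *with sign* per organ across subjects before
taking magnitudes, which cancels anthropometric-mismatch bias that does
not depend on strength. `run_study()` chains everything end to end.

```{r example}
library(ctdosim)
cfg <- study_config(n_subjects = 6, seed = 1, n_photons = 2e4)
report <- run_study(cfg)
print(report)
```

## 6. Numerical choices

* Compiled transport kernel; about 3 s per 10^6 photons on one CPU for a
  torso grid at 8 x 8 x 10 mm.
* R's RNG drives the kernel, so `seed` gives bit-identical dose grids and
  leaves the caller's RNG state untouched.
* Photon budgets: library coefficients are the precision bottleneck
  because small organs (thyroid, ~8 cm^3) collect few interactions; 10^6
  photons per library simulation give per-organ coefficient noise near
  1%, which is what the TCM-sweep experiment needs to resolve strength
  steps of 0.25.
* Attenuation fits for validation use a monoenergetic pencil beam: a
  pencil beam has no divergence, so the log-dose slope is the attenuation
  coefficient with no geometric correction.

## 7. Limitations

* Stylized anatomy: no real patient geometry, no arms, no positioning
  errors, no truncation, no metal or contrast.
* Kerma approximation (no electron transport) and a heuristic
  photoelectric/coherent split; scatter angles for coherent events are
  simplified. Absolute doses are plausible but not clinically validated —
  the package is built for *method comparison under a known ground
  truth*, where both routes share the same physics.
* Only longitudinal TCM; no overranging, no heel effect, no focal-spot
  size.
* The spectrum is an HVL-equivalent surrogate, not a measured spectrum.
* CTDIvol uses a soft-tissue cylinder instead of PMMA (see section 3).
* DICOM is supported only through JSON sidecars of slice headers
  (`extract_tube_currents()`); binary DICOM parsing is out of scope.
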