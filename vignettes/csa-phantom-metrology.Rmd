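---
title: "Quantifying coronary lumen areas on a synthetic resolution phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying coronary lumen areas on a synthetic resolution phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csaphantom)
```

## The measurement problem

Coronary endothelial function (CEF) is assessed from the vasomotor
response of a coronary artery — a relative change in lumen
cross-sectional area (CSA) of roughly 10–25% in healthy vessels, i.e. a
fraction of a square millimetre around a 3-mm vessel. Whether an imaging
chain (scanner + segmentation) can resolve such changes is a metrology
question: against a ground truth of precisely drilled lumens, how
accurate, how precise, and how *sensitive* (smallest detectable CSA
difference) is the measured area?

`csaphantom` implements the full evaluation loop in software:

1. **Phantom**: a 10-cm round block containing 110 drilled holes — 22
   diameters from 3.00 to 3.42 mm in 0.02-mm steps, 5 replicates each —
   placed collision-free at seeded random grid sites
   (`build_layout()`). Only the diameter ground truth enters the metrics,
   so hole positions are nuisance parameters; the generator enforces a
   centre spacing larger than any hole diameter so half-maximum contours
   can never merge.
2. **Image synthesis**: CT-like axial stacks and cine-MR-like frames of
   that phantom with protocol-dependent contrast, noise, blur and motion
   (`simulate_ct_stack()`, `simulate_mr_cine()`).
3. **Segmentation**: automatic detection and subpixel
   full-width-at-half-maximum (FWHM) contouring of every lumen
   (`segment_stack()`).
4. **Metrics**: accuracy (bias), precision, SNR, circularity, regression
   against drilled truth, and the ROC-AUC limit of detection
   (`csa_accuracy()`, `csa_precision()`, `measure_snr()`,
   `csa_regression()`, `csa_lod()`).
5. **Analytics**: closed-form acquisition-window motion bookkeeping
   (`window_displacement()` and friends).

## The image model

Both modalities start from the same noiseless *coverage field*: each
pixel holds the area fraction covered by a hole, computed by
supersampled rasterization (`rasterize_layout()`, default 8×8 subsamples
per pixel; 16 halves the residual error below 0.5% of a hole area). The
field is blurred by an isotropic Gaussian system PSF.

**CT.** `pixels = background_HU + ΔHU · blur(coverage) + noise`. The
contrast ΔHU is tabulated by iodine concentration and tube potential
(170/260/330/390 HU at 120 kVp, 250/370/460/560 HU at 100 kVp for
3/4/5/6% iodine). Noise is stationary Gaussian with

```
SD = SD_ref · sqrt(CTDI_ref / CTDI) · f_kVp · f_ASiR
```

with `SD_ref = 20` HU at the 20-mGy reference dose, 120 kVp and 0%
reconstruction strength; `f_kVp = 1.15` at 100 kVp (lower tube potential
pays a noise penalty at matched dose); and the iterative-reconstruction
strength acting purely as a first-order noise multiplier
`f_ASiR = 1.00 / 0.70 / 0.40` for 0/50/90%. Noise-texture changes of
iterative reconstruction are deliberately out of scope. 5-mm sections are
modelled as the average of eight contiguous 0.625-mm sections (noise SD
÷ √8). Real CT noise is spatially correlated; the background-SD noise
definition used throughout is insensitive to that correlation at this
scale, and the simplification is a documented limitation.

**MR.** The block (PMMA) gives no signal, so
`pixels = |S · blur(coverage) + complex Gaussian noise|` — Rician in the
lumen, Rayleigh in the background. `S` is set by the gadolinium
concentration through a calibration table (`default_snr_map()`): linear
from SNR 22 at 0.17 mmol/L to SNR 73 at 1.66 mmol/L (SNR 10 for undoped
water), so SNR ≈ 50 is reached near 1.0 mmol/L. No spoiled-GRE signal
equation is fitted — the relaxivity inputs it would need are not part of
the model. The Gaussian channel SD is `1/sqrt(2 − π/2)`, which makes the
*background magnitude* SD exactly 1; since the SNR estimator divides the
mean lumen signal by that background SD, the measured SNR reproduces the
calibration value (Rician mean bias is < 1% above SNR 10). Radial
k-space sampling and regridding are not simulated; motion enters in
image space (below).

**Motion.** A rigid sinusoid `x(t) = A sin(2πt/T)` with `A = 15` mm
(3 cm peak-to-peak) and `T = 1` s (60 bpm). During an acquisition window
of duration `T_w` centred at `t'` the phantom sweeps positions whose
normalized occupancy histogram, binned at the pixel pitch, is the 1-D
motion blur kernel (`motion_density_kernel()`). Windows default to the
extreme position `t' = T/4`, where motion is least; the kernel support
then equals the closed-form worst-case displacement
`A(1 − cos(π T_w / T))` to within one pixel. The CT window is half the
gantry revolution (0.14 s at 0.28 s/rev), the MR window is
`views_per_segment × TR` (95 ms at 19 × 5 ms). Per-heartbeat
repositioning jitter (sub-millimetre in vivo) is available as an extra
blur but defaults to 0.

## FWHM segmentation

Detection first estimates the rigid layout-to-image shift by circular
cross-correlation of the noiseless template with the section-averaged
image, then refines each hole centre as the above-local-median intensity
centroid in a window of radius one diameter. Per hole and section,
`segment_hole_fwhm()`:

- estimates the **peak** as the mean of the top intensity decile within
  0.5 mm of the centre, and the **background** as the median in the
  annulus 1.5–2.5 × the largest lumen radius (2.6–4.3 mm) — both robust,
  and both contrast-invariant in the sense that an affine intensity
  rescaling leaves the contour unchanged;
- sets the half-maximum level midway between them (if a pixel equals the
  level exactly it counts as *below*: half-open convention, implemented
  as an upward level nudge of 10⁻⁹ of the local contrast);
- extracts the subpixel iso-contour by linear interpolation on pixel
  edges (`grDevices::contourLines`, a marching-squares tracer) and keeps
  the innermost closed contour enclosing the centre;
- reports the shoelace area, polyline perimeter, isoperimetric
  circularity `4πA/L²` (≤ 1 by construction), and the mean lumen signal
  over the contour core (within 60% of the equivalent radius — keeping
  partial-volume edge pixels out of the SNR numerator).

Failures are explicit: no contour or non-positive contrast →
`low_contrast`; an enclosing contour clipped by the analysis window →
`window_too_small`. Failed measurements stay in the table with their
status and are excluded from summaries; a diameter retaining fewer than
half its measurements is not used as an LOD reference. Light Gaussian
pre-smoothing (σ = 0.5 pixel) is applied to MR frames by default and off
for CT; it is a flag, not an assumption, because interpolation is known
to worsen FWHM underestimation.

**Known bias.** The half-maximum level set of a *blurred disk* is
smaller than the disk: a curved edge pulls the half-level inward by
≈ σ²/(2R). With a 0.6-mm-FWHM PSF the continuum level-set area of a 3-mm
disk is 6.87 mm² against a drilled 7.07 mm² (−2.9%) — the FWHM criterion
systematically underestimates, and more so with larger PSFs, exactly the
direction reported for this family of segmentation algorithms. On top of
that, the marching-squares polygon inscribes the level set: at the
CT sampling of 0.39 mm (~9 pixels across a lumen) chord discretization
costs up to a further ~2%. Tests therefore compare the implementation
against a 20×-supersampled level-set oracle — within 1% at 0.2-mm
sampling, within 2.5% at 0.39 mm — rather than against the drilled area,
and separately pin the direction and magnitude of the nominal-area bias.

## Evaluation statistics

For a measurement table (110 holes × sections; e.g. 100 measurements per
diameter at 20 sections):

- **Accuracy**: per-diameter mean measured minus drilled CSA; summarized
  mean ± SD over the 22 diameters.
- **Precision**: per-diameter sample SD (n−1); summarized mean ± SD.
- **AUC**: midrank Mann-Whitney probability that a measurement from the
  larger hole exceeds one from the smaller (ties count ½), so
  `auc(x, y) + auc(y, x) = 1` identically.
- **LOD**: for each reference diameter, the smallest *nominal* CSA
  difference such that this pair and every larger difference from the
  same reference reaches AUC ≥ 0.95 (monotone closure guards against
  isolated lucky pairs). References whose largest pair fails get no LOD;
  if none succeeds, the condition is reported "LOD undetectable". The
  summary is the mean ± SD over references with a defined LOD — the
  averaging population is a design choice (the source material reports
  mean ± SD without defining it); per-reference detail and the undefined
  fraction are returned so any other aggregation can be formed. No
  multiple-testing correction is applied across the 231 pairs, matching
  the original analysis. Percentages use the 3-mm reference lumen:
  `100 · ΔCSA / (π · 1.5²)`.
- **SNR**: mean lumen signal over the background-ROI SD, per measurement.
  The background ROI is a corner patch of the image, outside the block
  circle and hence provably clear of every hole and its blur support.
- **Regression**: OLS of measured on nominal CSA over all valid rows.

## Choices where the design was open

- *Hole placement*: seeded sampling without replacement on a regular
  grid of pitch `min_spacing_mm` (default 6 mm, margin 5 mm). The
  original drilling map fixes positions we do not need to reproduce.
- *Drilling tolerance* (−0/+4 µm) is ignored: 0.1% of diameter, far
  below every simulated noise source.
- *PSF FWHMs* (CT 0.6 mm, MR 0.8 mm) are configurable surrogates for
  unpublished system responses; tests sweep them and assert directions,
  never absolute truth.
- *MR window TR*: the analytic default is 5 ms (giving the round 95-ms
  window used in the displacement bookkeeping); the acquisition-table
  value 4.9 ms is accepted everywhere. With A = 15 mm, T = 1 s and
  t′ = T/4 the closed form gives 1.43 mm for the CT window and 0.66 mm
  for the 95-ms MR window (0.64 mm with TR = 4.9 ms).
- *Peak-to-peak reading*: "maximum displacement 3 cm" is interpreted as
  peak-to-peak, consistent with A = 1.5 cm in the motion formula.
- *LOD indexing* uses nominal (drilled) differences, not measured ones:
  sensitivity is expressed against known truth.

## Problem sizes and runtime

All fixtures are generated in code. The test suite runs the full
110-hole phantom at up to 20 noiseless sections (2 200 segmentations)
and matched-seed condition pairs at 6–20 sections/frames; a full
72-condition factorial sweep (`ct_factorial_sweep()` + `run_sweep()`)
takes a few minutes and is not exercised by default — the mini-sweeps in
the tests cover the orchestration and determinism guarantees
(byte-identical CSVs for identical seeds).

## What passing tests do and do not show

The generator reproduces first-order contrast, noise magnitude,
partial-volume blur and rigid motion blur. It does **not** reproduce
correlated CT noise texture, iterative-reconstruction nonlinearities,
radial-MR streaking/undersampling, beam hardening, off-resonance, or
non-rigid cardiac motion. Consequently, passing tests validate the
*measurement pipeline* (segmentation + statistics + analytics) and the
qualitative protocol trends (precision/LOD improve with contrast and
dose; motion degrades precision, SNR and circularity; regression slopes
near unity); they do not certify scanner-specific absolute LOD values,
which depend on physical hardware and were explicitly left out of scope.

## A worked mini-example

```{r example, eval = FALSE}
lay <- build_layout(seed = 1)
p   <- ct_protocol(kvp = 100, ctdi_mgy = 20, iodine_pct = 6,
                   asirv_pct = 90, n_sections = 20)
st  <- simulate_ct_stack(lay, p, seed = 1)
tab <- segment_stack(st, lay)
summarize_performance(tab, st)
protocol_timing_report()
```
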