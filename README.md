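# csaphantom

Synthetic coronary phantom imaging and cross-sectional area metrology in R.

## The problem

Coronary endothelial function is assessed from the vasomotor response of a
coronary artery — a relative change in lumen cross-sectional area (CSA) of
10–25% around a ~3-mm vessel, i.e. fractions of a square millimetre. Whether
an imaging chain can resolve such changes is a metrology question. This
package answers it in software, for researchers evaluating CT angiography
and cine MR protocols: it simulates a drilled resolution phantom (110 holes:
22 diameters, 3.00–3.42 mm in 0.02-mm steps, 5 replicates each) imaged under
configurable contrast, dose, reconstruction-strength, and rigid-motion
conditions, segments every lumen automatically with the
full-width-at-half-maximum (FWHM) criterion at subpixel precision, and
computes the evaluation statistics:

- **accuracy** — per-diameter bias, mean(measured CSA) − π(d/2)²;
- **precision** — per-diameter SD of repeated measurements;
- **LOD** — the limit of detection: the smallest nominal CSA difference
  ΔCSA whose measurement distributions separate with Mann-Whitney
  ROC AUC ≥ 0.95, reported in mm² and as 100·ΔCSA/(π·1.5²) % of a 3-mm
  lumen;
- **SNR** (mean lumen signal / background SD), **circularity**
  (isoperimetric quotient 4πA/L²), and OLS **regression** of measured on
  drilled CSA;
- closed-form **motion analytics** for x(t) = A·sin(2πt/T): worst-case
  in-window displacement Δx = A|sin(ω(t′ ± T_w/2)) − sin(ωt′)|,
  slice-misalignment area error 1/cosθ − 1, heartbeat and tube-current
  bookkeeping.

## Worked example

Simulate the optimal CT protocol (100 kVp, 20 mGy, 6% iodine, 90%
reconstruction strength, 20 thin sections), segment all 110 holes, and
summarize:

```r
library(csaphantom)
lay <- build_layout(seed = 1)
p   <- ct_protocol(kvp = 100, ctdi_mgy = 20, iodine_pct = 6,
                   asirv_pct = 90, n_sections = 20)
st  <- simulate_ct_stack(lay, p, seed = 1)
tab <- segment_stack(st, lay)        # 2200 measurements, 100 per diameter
summarize_performance(tab, st)
```

```
protocol_id    ct_100kVp_20mGy_90asirv_6pct
accuracy_mean  -0.411     accuracy_sd   0.015
precision_mean  0.053     precision_sd  0.006
lod_mm2_mean    0.183     lod_mm2_sd    0.041
lod_pct_mean    2.59      lod_pct_sd    0.58
snr_mean       73.8       circ_mean     0.9924
n_valid        2200       n_failed      0
```

Reading: the FWHM criterion underestimates the drilled area by ~0.41 mm²
(a known, systematic partial-volume effect of half-maximum contouring on
blurred disks), repeated measurements of one diameter scatter by
0.053 mm², and under these favourable synthetic conditions CSA differences
of ~0.18 mm² (2.6% of a 3-mm lumen) are detectable at AUC ≥ 0.95.

The protocol timing report prints the closed-form motion numbers:

```r
protocol_timing_report()
#>   modality window_s displacement_mm heartbeats tube_current_ma
#>         CT    0.140            1.43          1          1428.6
#>         MR    0.095            0.66         13              NA
```

i.e. the 0.14-s CT half-revolution window sees more than twice the
displacement of the 95-ms segmented-MR window, and delivering 20 mGy
within one 0.14-s window would need a >1.4-A tube current.

Factorial protocol sweeps and figure-style outputs:

```r
conds  <- ct_factorial_sweep(n_sections = 6)   # 72 conditions
summary <- run_sweep(conds, lay, out_dir = "sweep_out")
report_curves(summary, "sweep_out")            # metric curves + tidy CSV
```

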