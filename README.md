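# cestb0

Static and dynamic B0 field-map correction for CEST MRI Z-spectra.

## The problem

Chemical exchange saturation transfer (CEST) MRI detects dilute labile
protons by saturating them at their chemical shift and reading out the
attenuated bulk-water signal. The resulting Z-spectrum,
`Z(Δω) = S_sat(Δω) / S0`, is quantified through the asymmetric
magnetisation transfer ratio

    MTRasym(Δω) = ( S_sat(−Δω) − S_sat(+Δω) ) / S0 ,

averaged over an offset band (e.g. 0.3–1.0 ppm). Because the direct water
saturation is steep near 0 ppm, MTRasym is acutely sensitive to where the
water line actually sits in each voxel: a local field offset ΔB0 shifts the
whole spectrum by `δω = ΔB0 / γ` (about 298 Hz/ppm at 7 T), and a temporal
frequency drift — gradient or shim heating, respiration, motion — moves it
*during* the scan, so that every Z-spectral point is mislocated by a
different amount.

`cestb0` implements six voxel-wise corrections:

**Static** (one map, whole spectrum shifted once)

- `minz` — water line from the minimum of the smoothing-spline interpolated
  Z-spectrum;
- `wassr` — Lorentzian fit of a low-power, high-resolution WASSR prescan;
- `gre2te` — dual-echo gradient-echo prescan phase map,
  `ΔB0 = ∠ Σ_l M2,l M1,l exp(i(Φ2,l − Φ1,l)) / (2π ΔTE)`, with
  Hermitian-inner-product multi-coil combination, 2D phase unwrapping and
  Hamming smoothing.

**Dynamic** (one map per Z-spectral point, each point corrected at its own
acquisition time)

- `cestgre2te` — the same dual-echo phase mapping applied to the CEST
  readout itself, at every saturation offset;
- `cestgre1te` — single-echo intrinsic mapping,
  `ΔB0 = ∠ Σ_l M1,l exp(i(Φ1,l − Φ_RX,l)) / (2π TE1)`, using time-invariant
  per-channel receive phase offsets
  `Φ_RX,l = (TE1 Φ2,l − TE2 Φ1,l)/(TE1 − TE2)` estimated once from the
  prescan;
- `nav2te` — dual-echo mapping of an interleaved navigator acquired before
  each labelling block.

A two-pool Bloch–McConnell simulator generates complete multi-coil complex
acquisitions (7 T, 61 offsets over ±4.5 ppm in alternating descending
order, TE 1.74/5.16 ms, a train of four 100-ms Gaussian pulses at 50% duty
and 2.0 µT RMS B1, WASSR prescan, smooth spatial ΔB0, linear drift, complex
Gaussian noise) with full ground truth, so every estimator can be validated
by parameter recovery.

## Worked example

Simulate the scan–rescan drift experiment (one run without drift, one with
60 Hz induced linearly over the ~13-min schedule, same seed and noise) and
compare corrections:

```r
library(cestb0)
cfg <- sim_config(seed = 1)           # 64x64, 8 channels, SNR 100
rep <- run_scan_rescan(cfg, methods = c("minz", "wassr", "gre2te",
                                        "cestgre2te", "nav2te"),
                       ranges = list(c(0.3, 1.0)))
print(rep)
```

```
<comparison_report> seed 1, induced drift 60.0 Hz, range 0.30-1.00 ppm
  minz       (static): +0.188% -> -1.292%  error 0.02466 %/Hz
  wassr      (static): -0.201% -> +16.752%  error 0.28256 %/Hz
  gre2te     (static): +0.011% -> +16.954%  error 0.28239 %/Hz
  cestgre2te (dynamic): +0.008% -> +0.184%  error 0.00293 %/Hz
  nav2te     (dynamic): +0.027% -> +0.090%  error 0.00106 %/Hz
```

Each row gives the ROI-mean MTRasym(0.3–1.0 ppm) without and with the
induced drift, and the discrepancy per Hz of drift. The drift wrecks the
statically corrected contrast (the prescan-based maps predate the drift:
+17% spurious asymmetry; the intrinsic minimum partially absorbs it), while
the per-offset dynamic corrections hold the discrepancy below 0.01 %/Hz.
The drifted field itself is tracked by the intrinsic maps:

```r
acq <- generate_acquisition(cfg)
fd  <- fit_drift(dynamic_series(acq, "cestgre2te"),
                 erode_mask(default_roi(acq), 4))
fd$rate_hz_min * max(acq$schedule$timestamp_s) / 60   # ~60 Hz recovered
```

Datasets round-trip losslessly through NIfTI + JSON (`save_acquisition()` /
`load_acquisition()`), and a thin CLI wraps the pipeline
(`inst/cli/cestb0 {simulate,mapb0,correct,asym,scanrescan}`).

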