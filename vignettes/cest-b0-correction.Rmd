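---
title: "Field-map correction of CEST Z-spectra: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-map correction of CEST Z-spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cestb0)
```

## Why B0 correction decides what CEST measures

A CEST experiment saturates at a nominal offset $\Delta\omega_{RF}$ from
water and quantifies the asymmetry of the normalised Z-spectrum,
$MTR_{asym}(\Delta\omega) = Z(-\Delta\omega) - Z(+\Delta\omega)$, over a
band of offsets. A local field deviation $\Delta B_0$ displaces the water
line by $\delta\omega = \Delta B_0/\gamma$, so the pulse applied at
$\Delta\omega_{RF}$ actually acts at
$\Delta\omega_{RF} - \delta\omega$ relative to water. Near the water line
the Z-spectrum falls almost linearly, so a common-mode shift $\delta$
injects a spurious asymmetry of roughly
$2\,\delta\, Z'(\Delta\omega)$ — at 7 T (298 Hz/ppm) and a Z-slope of
~0.45/ppm, every Hz of uncorrected shift is worth about 0.3% of MTRasym in
the 0.3–1.0 ppm band. Static corrections estimate one $\delta\omega$ per
voxel and shift the whole spectrum; dynamic corrections estimate one per
Z-spectral *point*, which is what makes them robust to drift during the
scan.

## The forward model the simulator implements

`generate_acquisition()` synthesises, directly in image space, the
per-channel complex signal at saturation offset $k$ (timestamp $t_k$),
echo $j$:

$$ S_{l,j}(\mathbf{x}) = m_l(\mathbf{x})\, S_0(\mathbf{x})\,
   Z_k(\mathbf{x})\, e^{\,i\,(2\pi f(\mathbf{x},t_k)\,TE_j +
   \Phi_{RX,l}(\mathbf{x}))} + \varepsilon, $$

with $f = \Delta B_0(\mathbf{x}) + d(t_k)$ the spatial field polynomial
plus a linear drift $d(t) = r\,\max(t,0)/60$, coil magnitudes $m_l$
(Gaussian lobes, positive sum-of-squares everywhere), receive phases
$\Phi_{RX,l}$ (low-order polynomials within $(-\pi,\pi]$), and i.i.d.
complex Gaussian noise whose standard deviation is calibrated to the mean
channel-combined unsaturated magnitude (`snr = 100` by default). The
Z-value of a voxel is the two-pool Bloch–McConnell spectrum evaluated at
`applied − f/(Hz per ppm)` — shift invariance is exact by construction and
is exploited by computing the spectrum once on a fine offset grid (0.02 ppm
step) and interpolating per voxel.

Images are synthesised in image space because every correction operates on
reconstructed images; k-space traversal, EPI distortion and
readout-gradient delays are not modelled. Other idealisations: no T2*
decay between echoes, no B1 inhomogeneity, no motion, no respiration, and
no semisolid MT pool. Passing tests therefore demonstrate correctness of
the estimators and the drift phenomenology, not robustness to every
confound of real tissue.

### Saturation physics

The two-pool Bloch–McConnell equations (water + optional dilute solute,
exchange rate $k_{sw}$, fraction $f_s$, shift $\Delta\omega_S$) are
integrated by piecewise-constant propagation: each Gaussian pulse
(truncated at $3\sigma$) is discretised into segments and each segment
advanced with the matrix exponential of the homogeneous-augmented 7×7
system; inter-pulse gaps evolve free relaxation and exchange; readout
follows the last pulse; each Z-point starts from equilibrium (the 10-s
recovery delay exceeds $8\,T_1$). The amplitude is normalised so the RMS
B1 over the whole train (pulses and gaps: 700 ms for four 100-ms pulses at
50% duty) equals the stated `b1rms`.

The number of segments matters more than is obvious: a piecewise-constant
waveform has spectral replicas at the segment rate $n/t_p$, and if that
rate falls inside the sampled offset range the discretisation itself
saturates spuriously. Thirty-two segments per 100-ms pulse put the replica
at ~320 Hz ≈ 1.07 ppm at 7 T — inside the spectrum, with Z errors up to
17%. The default is 256 segments (replica at ~8.6 ppm), which agrees with
512 segments to ~1×10⁻⁵; the convergence test halves the segment width and
requires <0.1% movement.

Right on resonance the pulse train can drive $M_z$ slightly negative; a
scanner records that as a π phase flip, and magnitude detection measures
$|M_z|$. The simulator keeps the signed value in the complex signal and
stores the magnitude-detected spectrum as the clean ground truth.

### Study conditions and defaults

| Parameter | Default | Why |
|---|---|---|
| Field / conversion | 7 T, 42.577 MHz/T → 298.0 Hz/ppm | ultra-high-field CEST regime |
| Offsets | 61 over ±4.5 ppm, 0.15 ppm, alternating descending | mirrored offsets sampled back-to-back minimise differential drift |
| Readout | TE 1.74 / 5.16 ms, TR 9.5 ms/line | dual-echo gradient echo; ΔTE sets the 292 Hz aliasing period |
| Saturation | 4 × 100 ms Gaussian, 50% duty, 2.0 µT RMS | standard pulsed amide-range labelling |
| WASSR | ±0.8 ppm, 0.05 ppm steps (0.01 phantom), 1 × 100 ms, 0.2 µT | direct saturation only; CEST/MT negligible |
| Water pool | T1 1.2 s, T2 40 ms | 7 T white-matter values |
| Solute | +3.5 ppm, k 30 s⁻¹, f 9×10⁻⁴, T2 10 ms | amide-like dilute pool |
| Drift | 60 Hz total over the ~13-min schedule (≈4.75 Hz/min) | upper range of reported gradient-heating drifts |
| Grid / coils | 64×64, 8 channels | scaled from 32-channel head coils to keep tests fast |
| Timing | navigator 1 s + train 0.7 s + readout 0.61 s + 10 s recovery per point | gives the ~13-min schedule the drift is defined over |
| Noise | SNR 100 on the combined S0 magnitude | moderate-SNR single-slice acquisition |

The phantom preset (`phantom_config()`) removes the solute (T1 0.9 s, T2
150 ms), samples 41 offsets over ±2.2 ppm (0.11 ppm) and tightens the
WASSR step to 0.01 ppm; with no exchanging or semisolid pool the corrected
MTRasym must be zero up to noise, which is the cleanest accuracy probe for
the corrections themselves.

## Estimators

**Dual-echo phase mapping.** The Hermitian inner product
$\sum_l M_{2,l} M_{1,l} e^{i(\Phi_{2,l}-\Phi_{1,l})}$ cancels any
channel-constant phase in the echo difference exactly (tested to
10⁻¹² Hz), and its angle divided by $2\pi\,\Delta TE$ is the field in Hz.
The sign convention is $\Phi = +2\pi\,\Delta B_0\,TE + \Phi_{RX}$
(positive field ⇒ phase grows with TE), validated against the simulator
rather than assumed.

**Phase unwrapping.** The wrapped-gradient divergence is inverted by a
discrete Poisson solve with reflective boundaries (FFT on the
even-symmetric extension), then made congruent with the input modulo
$2\pi$ per voxel; the global $2\pi k$ constant is fixed so most voxels
keep their wrapped value. Fields beyond $1/(2\Delta TE)$ (±146 Hz at
ΔTE 3.42 ms) stay aliased unless a spatial ramp lets the unwrapper resolve
them; no temporal unwrapping is attempted because the drift per Z-point
(<0.1 Hz) is far below the aliasing period.

**Coil phase offsets.** $\Phi_{RX,l}$ follows from extrapolating the two
echo phases to TE = 0, $(TE_1\Phi_{2,l} - TE_2\Phi_{1,l})/(TE_1-TE_2)$, in
which the field term cancels algebraically. Voxels are masked at 5% of the
99th-percentile combined magnitude (the threshold is a package choice);
outside the mask the offsets are extrapolated from a GCV tensor-product
spline (`mgcv::gam`) fitted to the unit phasor — smoothing the phasor
rather than the phase avoids wrap discontinuities. Inside the mask the raw
estimate is kept by default, because it is algebraically exact on
noiseless data; `smooth = "full"` replaces it with the smooth.

**Magnitude-based referencing.** `minz_center()` fits a GCV smoothing
spline per voxel and takes the argmin on a ≤0.001-ppm grid; the effective
degrees of freedom are capped at 25 so the spline cannot chase noise, ties
break towards the smallest $|\delta\omega|$ and boundary minima are
flagged invalid. `wassr_center()` fits the Lorentzian dip
$b - a\Gamma^2/(\Gamma^2+4(\Delta\omega-\delta\omega)^2)$ by
Levenberg–Marquardt with data-driven starts; non-convergence flags the
voxel.

**Dynamic series and the near-water rule.** The intrinsic methods lose SNR
where the labelling saturates water ($Z \to 0$), so maps measured at
$|\Delta\omega| < 0.33$ ppm are flagged low-confidence and replaced
voxel-wise by linear temporal interpolation between the nearest valid
maps. The navigator sees unsaturated water and needs no exclusion. Drift
fitting drops the flagged maps instead of using the interpolated copies:
they carry no independent field information, and because the near-water
offsets are acquired last, keeping the clamped replacements biases the
fitted ramp low.

**Correction resampling.** Both correction modes run through one
resampler: each measured point is a sample of the true spectrum at
`applied − δω`, and the (true offset, Z) knots are interpolated onto the
nominal grid with a *monotone Hermite* (Fritsch–Carlson) spline.
A polynomial spline was measured to overshoot on the steep walls of the
direct-saturation dip and leak a systematic ~0.02–0.04% asymmetry into the
phantom null at exactly the scale of its noise floor; the shape-preserving
interpolant reduces that about four-fold at a small (<10⁻³ in Z) cost in
smooth regions. Duplicated knots (possible after large drift) are
averaged; queries outside the covered range are marked missing and
excluded from range means rather than extrapolated; voxels with
$|\delta\omega|$ beyond half the spectral span are flagged uncorrectable.
A constant per-offset series reproduces the static path bit for bit
because both modes share the code.

## The scan–rescan experiment

`run_scan_rescan()` generates two acquisitions from one seed differing
only in the induced drift (0 vs 60 Hz — same noise realisation), corrects
both with each requested method, and reports the ROI-mean MTRasym
discrepancy divided by the total drift. On the default conditions the
dynamic methods stay below 0.01 %/Hz while the prescan-based static
corrections reach ~0.28 %/Hz and the intrinsic minimum partially absorbs
the drift (~0.02 %/Hz, with the opposite sign of bias). The ROI defaults
to the object support eroded by 4 voxels: the field maps are smoothed
without masking, so the boundary ring mixes background phase; in the
simulated disc the background is pure noise, and including the ring would
attribute its artifacts to the corrections.

The ~0.28 %/Hz static rate deserves a note: it follows directly from the
simulated Z-slope (~0.45/ppm in the 0.3–1.0 ppm band) of the MT-free
two-pool white-matter model. In vivo spectra are flattened by the
semisolid MT background and tissue heterogeneity, which this model
deliberately excludes, and in-vivo distortion rates reported for
prescan-based corrections are correspondingly lower (~0.2 %/Hz). The
package reports what its model produces rather than rescaling to match.

## Problem sizes

Module tests run on 24×24 grids with 21 offsets and 4 channels; the
validation experiments use the full 64×64, 61-offset, 8-channel
conditions (a scan–rescan pair with five correction methods takes well
under a minute on one CPU). All randomness flows from a single seed; the
same configuration and seed reproduce every number exactly.

## Known limitations

- Two pools only: no semisolid MT, no NOE; MTRasym magnitudes are not
  in-vivo-calibrated (drift *sensitivities* are the object of study).
- Single 2D slice; no motion, B1 error, EPI distortion or
  readout-gradient-delay phase errors (the latter are a known residual of
  navigator-based mapping left uncorrected here as well).
- Spillover/labeling-efficiency compensation of MTRasym is out of scope;
  the asymmetry is reported as measured.
- The aliasing ambiguity of phase maps is resolved spatially only; a
  uniform field beyond ±146 Hz (ΔTE 3.42 ms) reports wrapped.
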