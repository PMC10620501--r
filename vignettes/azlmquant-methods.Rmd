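---
title: "Quantifying endocytosed Syp-SEP around active-zone-like membranes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endocytosed Syp-SEP around active-zone-like membranes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(azlmquant)
```

## The measurement problem

Presynaptic terminals retrieve fused synaptic-vesicle membrane by several
endocytic routes — clathrin-mediated endocytosis (CME, seconds to tens of
seconds), activity-dependent bulk endocytosis (ADBE, after strong
stimulation), and ultrafast endocytosis (UFE, within ~100 ms, only near
physiological temperature). Distinguishing *where* and *when* each route
retrieves a vesicle protein requires imaging single active zones live.

The experimental configuration this package quantifies solves that with
three tricks. First, an active-zone-like membrane (AZLM) is induced flat
against a neuroligin-coated coverslip, so the active zone lies in the TIRF
evanescent field (axial decay length ~151 nm) and is marked by CAST-RFP in
the red channel. Second, synaptophysin is tagged on its luminal face with
super-ecliptic pHluorin (Syp-SEP), which is fluorescent at pH 7.4 and
quenched at acidic pH. Third, a U-tube perfusion switches the extracellular
pH to 6.0 for 700 ms windows (7.4→6.0 in ~100 ms, back in ~200 ms): during
a window, all surface SEP is quenched, and the only green signal left comes
from *recently endocytosed, not yet re-acidified* vesicles near the
coverslip. Each pH 6.0 window is therefore a snapshot of fresh endocytosis
at that moment.

The package implements the full measurement chain for such recordings and
a forward simulator with ground truth, so every stage is verifiable without
microscope data.

## The analysis chain

Stages run in a fixed order (`run_analysis()`):

1. **Drift compensation.** Stage drift is estimated on the stable CAST
   channel by FFT cross-correlation of every frame against frame 1, with a
   1-D parabolic refinement of the correlation peak in each axis; the same
   (possibly fractional) shifts are applied to both channels by bilinear
   interpolation. Pixels exposed at the field edge are filled with the
   frame's median — its background level — so they cannot survive the later
   background-referenced subtraction; using a plain mean here would imprint
   the bright-signal average onto the border.
2. **Photobleach correction.** A double-exponential bleach model
   $B(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2}$, $a_1 + a_2 = 1$, is
   fitted to a no-stimulation recording (`fit_bleach()`) and divided out
   (bleaching is a multiplicative loss of fluorophores, so correction
   divides rather than subtracts, and the model carries no additive
   offset — offsets belong to background subtraction). A constant trace
   returns the identity model; effectively mono-exponential traces fit
   degenerately ($a_2 \approx 0$ or $\tau_1 \approx \tau_2$) and are
   accepted.
3. **Thresholding.** Detection thresholds are background mean + k·SD with
   k = 3, recomputed per analysis image. With an explicit signal-free
   rectangle ROI the plain mean/SD are used. The automatic default
   estimates the background as the whole-frame median and scaled MAD:
   fluorescent signal occupies a sparse minority of pixels, so these
   robust estimators recover the background moments. (Selecting the
   lowest-intensity quantile of the same frame as a "background region"
   was rejected: the order-statistic selection biases both mean and SD
   low, and in practice pushed half the frame above threshold.)
4. **AZLM segmentation.** 8-connected supra-threshold components of one
   CAST image, area-gated inclusively to 0.098–0.38 µm². The gate is
   evaluated on the exact area (pixel count × pixel area), no rounding.
   Detection uses the drift-reference (first) CAST frame rather than a
   temporal mean: the threshold is defined per image, and averaging T
   frames would shrink the background SD by √T and dilate the
   supra-threshold region accordingly. CAST moves little over a recording
   (the package reports its centroid displacement), so one frame
   represents the AZLM well.
5. **Window averaging and subtraction.** Five frames fall in each 700 ms
   pH 6.0 window at the 120 ms frame interval; the later four are
   averaged (the first is discarded while the solution exchange
   completes), and the result is labeled with the time of the first
   averaged frame — a window opening 3 s after stimulation is analyzed
   "at 3.24 s". The pre-stimulus pH 6.0 average is subtracted to remove
   stimulus-insensitive intracellular signal (endoplasmic reticulum,
   resting endosomes); negative values are retained.
6. **Cluster segmentation and watershed splitting.** Syp-SEP clusters are
   8-connected components strictly above threshold with area strictly
   greater than 0.098 µm². Merged clusters with several intensity peaks
   are split: the cluster is smoothed (Gaussian, σ = 1 px), local maxima
   are ranked by topographic prominence (computed by a persistence
   union-find over descending intensity), maxima with prominence of at
   least 1 background SD become markers, and pixels flood to the marker
   basins in descending intensity order. A pixel adopts the label of its
   highest already-labeled 8-neighbour (water reaches it from the steepest
   side first); equal-height ties fall to the lower label id, which makes
   the partition deterministic. Children always partition the parent's
   pixel set exactly.
7. **Exclusion.** A cluster whose intensity rises during a pH 6.0 window
   reflects Syp arriving in the evanescent field from deeper in the
   terminal rather than fresh endocytosis; clusters whose last
   intra-window sample exceeds the first by more than 3 background SD are
   flagged excluded. The qualitative rule ("an increase from background
   while pH is 6.0") is operationalized as this last-vs-first comparison.
8. **Measurement.** Intensity-weighted centroids; signed distances from
   centroid to the nearest AZLM boundary (negative inside the mask,
   positive outside, magnitude = minimum distance to boundary-pixel
   centers, no sub-pixel contour interpolation — documented accuracy half
   a pixel); per-cluster maximum intensity, area, and their ratio (the
   density measure that separates CME-concentrated from bulk-derived
   vesicles); nearest-centroid displacements between trials; F/F_pre and
   F − F_before time courses; post-peak mono-exponential decay constants.

Measurements comparing near-physiological-temperature data with
room-temperature data are rescaled with the single-molecule brightness
ratio (`temperature_correct()`; SEP is ~32% brighter at RT, 2900 vs
2200 a.u. per molecule on the reference scale).

## Calibrations

Three instrument calibrations are implemented (`calibrate` functions):

- **Single-molecule intensity.** Traces of immobilized SEP are fitted by
  binary-segmentation change-point detection; a split is accepted when the
  level change exceeds 3× a robust noise SD (MAD of first differences /
  √2). Only traces with exactly one downward step — the single-molecule
  signature — contribute; aggregates (staircases) are rejected.
- **Evanescent decay length.** $I_0 e^{-z/\lambda}$ fitted to a z-series
  of a dye-filled electrode tip raised in 125 nm steps (0–625 nm). A
  single mono-exponential without offset is used, matching the single
  length constant the configuration is characterized by; the fit is exact
  on noiseless data.
- **Solution-exchange time.** The 10–90% duration of the quench or
  recovery transition, linearly interpolated between samples. "About
  100 ms" names no criterion; 10–90% is the conventional one.

## The synthetic acquisition simulator

The simulator is first-class, tested code. Its defaults *are* the study
conditions; they are not tuned per experiment.

**Event model.** The expected number of fusion events for a p-pulse train
is $N(p) = N_{max}(1 - e^{-p/p_0})$ with $N_{max} = 123$ vesicles and
$p_0 = 100$ pulses, chosen so that a 5-pulse stimulus fuses ~6 vesicles
(the configuration's own estimate) while 5:20:50 pulses stay
near-proportional and 125 pulses is clearly sub-proportional
(N(125)/N(50) = 1.8) — the readily-releasable-pool saturation seen
experimentally. The realized count is Poisson; fusion positions are
uniform in the AZLM disc; a binomial fraction (default 0.8) of fused
vesicles is retrieved as endocytosis events placed on an annulus around
the disc edge with mode-specific radial offsets (CME ~ N(100, 80) nm,
ADBE ~ N(140, 80) nm, UFE ~ N(20, 60) nm outside the edge). UFE is gated
by a hard 30 °C threshold (the configuration contrasts 21–23 °C with
31–32 °C only) and occurs within 0.3 s of stimulation onset; CME/ADBE
events occur 0.5–10 s after. Endocytosed vesicles sit 50–150 nm above the
coverslip (the presynaptic cytosol starts ~50 nm up) and re-acidify with
time constants uniform in 3–15 s (the cited range; the distribution is
unspecified, so the least-informative choice). Each vesicle carries 32
synaptophysin copies by default (typical vesicle stoichiometry); ADBE and
UFE events carry 4 vesicle-equivalents of membrane (a 100 nm vesicle has
(100/50)² = 4× the area of a 50 nm vesicle).

**Optics and rendering.** Point emitters are rendered as pixel-integrated
Gaussians (PSF σ 130 nm default), so an unclipped blob's summed intensity
equals its amplitude exactly; axial position attenuates by
$e^{-z/\lambda}$ with λ = 151 nm. Surface Syp after fusion spreads as a
Gaussian of σ(t) = rate·√(t − t₀) (rate 150 nm/√s default; diffusion out
of the AZLM is documented but unrated) and leaves the footprint with a
~20 s time constant, reproducing the post-stimulus pH 7.4 decay. Surface
fluorophores are quenched to `quench_residual` (default 0) during pH 6.0
frames; internalized ones are insensitive to bath pH but fade with their
acidification constant. The pixel size default is 66.7 nm (150× objective
× 1.6 intermediate lens with a 16 µm-pixel camera). The AZLM disc in the
CAST channel uses the closed form for a disc convolved with a Gaussian
(a noncentral-χ² tail), drifts with the stage, and does not bleach.

**Noise.** EMCCD response is simplified to
Poisson(signal/photon_scale)·photon_scale + Gaussian read noise, with
EM-gain excess noise folded into `photon_scale`; this preserves shot-noise
scaling, which is what the thresholding stages are sensitive to. The pH
transition is a logistic in time parameterized by its 10–90% duration
(the transition is smooth and monotone; only "about 100/200 ms" is
characterized).

**CAST contrast calibration.** The analysis defines the AZLM as the
supra-threshold CAST area, so the detected disc size depends on rendered
contrast. The default contrast (`cast_amplitude_for_gate()`) places the
mean + 3SD threshold contour of the blurred disc a quarter pixel outside
the nominal edge. The reasoning: edge distances are measured as the
minimum distance to boundary-pixel *centers*; at any angle the outermost
supra-threshold center lies uniformly within one pixel inside the
contour, and the minimum over the few boundary pixels spanning the
nearest angular neighbourhood sits about a quarter pixel inside the
contour in expectation. A contour at r₀ + px/4 therefore centers the
estimator on the nominal edge. With this calibration the full
segmentation–centroid–distance pipeline recovers a 100 nm true offset
with a residual bias under ~10 nm at SNR ≥ 5 (pixel 66.7 nm), within the
half-pixel accuracy the distance definition allows.

**Timeline grid.** The simulator keeps one continuous 120 ms frame grid
per recording, so pH-window openings must sit on that grid for the
5-frames-per-window bookkeeping. The default 50-pulse scenario uses
stimulation at 5.04 s and window offsets −4.08, 3, 6.96, 15, 27 and 39 s
(analyzed at −3.84, +3.24, +7.20, +15.24, +27.24, +39.24 s). Real
acquisitions restart a burst per window and can label windows at
arbitrary offsets (e.g. −3.88 or +7.24 s); a single continuous grid
reproduces the +3.24 s convention exactly and approximates the others to
within one frame.

**What the simulator does not emulate.** Vector PSF models, pool
depletion across repeated trials, clathrin biochemistry, 3-D rendering,
flat-field/vignetting structure, and correlated (non-white) camera noise.
Passing recovery tests on these synthetic data therefore demonstrates
that the *measurement chain* is unbiased under the stated forward model —
not that the forward model captures every property of real recordings.

## Numerical and convention choices

- Pixel indices are 1-based (R convention); physical coordinates in nm
  are measured from the center of pixel (1, 1), x along columns, y along
  rows; areas are reported in µm².
- A frame at time t belongs to a pH window iff start < t ≤ start +
  duration (with a 10⁻⁹ s float guard); this yields exactly 5 frames per
  700 ms window at 120 ms.
- Components use 8-connectivity: at the 0.098 µm² gate scale (~22
  pixels), 4-connectivity would split diagonal blobs.
- The AZLM gate is inclusive at both bounds; the Syp cluster gate is
  strict (> 0.098 µm²), mirroring the different phrasings of the two
  rules.
- Subtraction direction is post-stimulus minus pre-stimulus: the stated
  purpose (removing stimulus-insensitive organelle signal) forces this
  direction even though the describing sentence can be read inverted.
- F_pre for F/F₀ normalization is the mean over all pre-stimulus pH 7.4
  frames; per-cluster normalization is used where a denominator is
  ambiguous between cluster and cell.
- The exocytosis centroid at pH 7.4 (0.12 s after stimulation) uses the
  entire merged Syp-positive area without watershed splitting, since it
  reflects many simultaneously fused vesicles.
- All nonlinear fits use Levenberg–Marquardt (`minpack.lm::nlsLM`) with
  box constraints and log-linear initialization where applicable; ties in
  watershed flooding and plateau assignment go to the lower label id;
  stacks store intensities rescaled to [0, 1] in 32-bit float TIFF with
  the affine transform recorded in the JSON sidecar (lossless to float32
  precision).
- Problem sizes used by the test suite and the acceptance script (64×64
  or 48×48 pixel fields, 100-frame recovery sets, 200 z-series, 114
  bleach traces, 50 decay traces) were chosen as the smallest sets at
  which the estimators' standard errors are well inside the stated
  recovery bands.

## Known limitations

- Edge distances are quantized at the half-pixel level by construction;
  sub-pixel contour interpolation is deliberately not attempted.
- The influx-exclusion rule (last vs first intra-window sample) also
  flags genuine endocytosis that occurs *during* a window; the
  experimental rule shares this property, but simulated scenarios with
  many mid-window events will show high exclusion rates.
- Drift estimation assumes a dominant static structure in the reference
  channel; an empty CAST field is rejected rather than guessed at.
- The bleach model is fitted on a separate no-stimulation recording and
  assumed transferable, as in the experimental procedure.
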