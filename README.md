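# azlmquant

Quantification of endocytosed synaptophysin-pHluorin around
active-zone-like membranes in TIRF microscopy.

## What it does

Synaptic vesicles fuse at presynaptic active zones and their membrane is
retrieved by several endocytic routes (clathrin-mediated, bulk,
ultrafast). One way to watch this live is to grow an active-zone-like
membrane (AZLM) flat on a neuroligin-coated coverslip, mark it with
CAST-RFP, tag synaptophysin with the pH-sensitive GFP variant
super-ecliptic pHluorin (Syp-SEP), and image in TIRF while a U-tube
rapidly switches the extracellular pH to 6.0 for 700 ms windows. At
pH 6.0 all surface SEP is quenched, so the remaining green signal marks
recently endocytosed, not-yet-acidified vesicles around the AZLM.

`azlmquant` implements the complete quantification for such recordings:

- **preprocessing** — stage-drift compensation (FFT cross-correlation
  with sub-pixel refinement), double-exponential photobleach correction
  `I(t) = I0 (a1 e^(-t/tau1) + a2 e^(-t/tau2))`, per-image
  mean + 3 SD background thresholds;
- **segmentation** — 8-connected supra-threshold components, AZLM area
  gate (0.098–0.38 µm², inclusive), Syp-SEP clusters (> 0.098 µm²),
  marker-based watershed splitting of merged clusters;
- **quantification** — pH 6.0 window averaging (later 4 of 5 frames,
  analyzed "at 3.24 s" for a window opening at +3 s), pre-stimulus
  subtraction, influx exclusion, intensity-weighted centroids, signed
  distances to the AZLM edge, max-intensity/area/density metrics,
  trial-to-trial nearest-centroid displacement, F/F_pre and F − F_before
  time courses, post-peak decay constants, RT/PT brightness rescaling;
- **calibration** — single-molecule intensity via change-point
  step-bleach detection, evanescent decay length `I0 e^(-z/lambda)`,
  10–90% solution-exchange times;
- **simulation** — a seeded two-channel forward model (PSF, evanescent
  attenuation, pH quenching, acidification, bleaching, drift, EMCCD-like
  noise) with a full ground-truth sidecar, so every stage is testable
  without microscope data.

Results are tidy per-cluster tables (`edge_distances.csv`,
`cluster_metrics.csv`, `timecourses.csv`, `drift.csv`) keyed by recording
id, timepoint label, and cluster label, with an `excluded` flag; one row
per cluster-measurement. Statistical hypothesis testing is deliberately
out of scope — the tables are the interface.

## Worked example

Simulate a 16 s, 50-pulse recording (one pre-stimulus pH 6.0 window,
post-stimulus windows at +3 and +6.96 s) and run the full analysis:

```r
library(azlmquant)

tl  <- scenario_timeline(duration = 16, ph6_offsets = c(-4.08, 3, 6.96))
sim <- run_simulation("sim1", seed = 11, timeline = tl)
res <- run_analysis(sim$sep, sim$cast, out_dir = "results1")

length(res$azlm)
ed <- res$edge_distances[!res$edge_distances$excluded, ]
aggregate(signed_nm ~ timepoint_label, ed,
          function(x) c(n = length(x), mean = round(mean(x))))
```

```
[1] 1
  timepoint_label signed_nm.n signed_nm.mean
1            8.28           1             76
2           12.24           2             48
```

One AZLM is detected; the non-excluded endocytic clusters at the two
analysis timepoints (8.28 s = stimulation + 3.24 s, 12.24 s =
stimulation + 7.20 s) sit 48–76 nm *outside* the AZLM edge (positive
sign), as expected for endocytosis in the active-zone periphery.
Clusters whose intensity rises during a pH 6.0 window are flagged
`excluded` and dropped from the aggregate.

Calibrations work the same way from simulated inputs:

```r
zs <- simulate_ztip_series(151, cv_noise = 0.03, seed = 2)
fit_length_constant(zs$z_nm, zs$intensity)   # 156.0 nm (3% noise, 1 series)

traces <- simulate_single_molecule_traces(114, amplitude = 2900,
                                          read_noise_sd = 80,
                                          n_frames = 100, seed = 3)
smi <- single_molecule_intensity(traces)
sprintf("%.0f +/- %.0f a.u. (n = %d)", smi$mean, smi$sem, smi$n)
# "2904 +/- 2 a.u. (n = 114)"
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/azlm-pipeline.R`:

```sh
Rscript azlm-pipeline.R simulate --out sim1 --seed 4
Rscript azlm-pipeline.R analyze --sep sim1/sep.tif --cast sim1/cast.tif --out results1
Rscript azlm-pipeline.R compare-trials --a t1/edge_distances.csv --b t2/edge_distances.csv --out disp.csv
```

## Documentation

The methods vignette (`vignettes/azlmquant-methods.Rmd`) describes the
analysis chain, the simulator's forward model and its calibrations, the
numerical conventions, and known limitations. Every exported function
carries roxygen documentation.
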