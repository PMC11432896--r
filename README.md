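# utedce

Sliding-window radial UTE DCE-MRI reconstruction and model-free
enhancement analysis for preclinical lung imaging.

Dynamic contrast-enhanced (DCE) MRI of the rodent lung at high field has
to work around sub-millisecond lung T2*, continuous motion, and a contrast
bolus that transits in seconds. `utedce` implements a complete desk-scale
pipeline for the approach used in bleomycin-injury rat studies:
continuous multi-slice radial ultra-short echo time (UTE) acquisition with
a tiny-golden-angle spoke ordering, retrospective sliding-window
reconstruction, and a model-free analysis of relative signal enhancement.
Because raw animal data cannot be redistributed, the package ships a
digital dynamic rat-lung phantom whose k-space is simulated by exact
nonuniform DFT, so every stage is testable against ground truth.

The pipeline, stage by stage:

* **Trajectory** — tiny-golden-angle increments
  `ψ_N = 180°/(φ + N − 1)` (order 7 gives the protocol's 23.63°),
  center-out half-spokes normalized to [−0.5, 0.5], ramp density
  compensation `w ∝ |k|` with a configurable DC-sample floor.
* **Reconstruction** — density-compensated Kaiser–Bessel gridding
  (oversampling 1.5, width-4 kernel, analytic deapodization, zero-fill 2
  to 0.302 mm apparent pixels), and a monotone-FISTA solver for
  `min ‖√W(Ax − y)‖² + λ₁‖Ψx‖₁ + λ₂‖x‖²` with an orthonormal Daubechies-4
  sparsity transform and the protocol weights λ₁ = 0.00536, λ₂ = 0.0016
  (ratio 3.35).
* **Sliding window** — frames of 90 spokes advancing by 60; at the
  38-slice effective repetition time of 114 ms that is 10.26 s of data per
  frame, 6.84 s apart.
* **DCE analysis** — baseline from frames 1–50, relative enhancement
  `RE = (S − S0)/S0`, corner-background drift trace subtracted from
  curves, seven enhancement classes at edges {1, 2, 3, 4, 8, 12}, bin and
  lung volumes, low-enhancement fraction.
* **Morphometry / QC** — intensity-histogram lesion volume on a
  3000-spoke baseline image, histology tissue fraction at the
  scanner-scale threshold 900, SNR with Rayleigh correction.
* **Phantom** — compartments (body, parenchyma, lesion, vessels) with
  SPGR signals, uptake×washout enhancement courses, seeded complex noise
  and optional receiver drift; presets `control`, `bleo_d7`, `bleo_d28`
  calibrated to the study's lung volumes (4.4 / 5.5 / 6.5 ml).

## Worked example

A desk-scale fibrotic-stage (day-28 preset) run from the shell:

```sh
Rscript inst/scripts/run_pipeline.R --config demo_config.yaml --out demo_run
```

with `demo_config.yaml`:

```yaml
preset: bleo_d28
seed: 1
matrix_size: 48
n_slices: 2
n_profiles: 6200
time_scale: 0.0667
zero_fill: 1
baseline_spokes: 3000
```

prints

```
lung volume: 0.87 ml | low-enhancement fraction: 48.0% | lesion: 0.08 ml | SNR: 91.1
outputs in demo_run
```

and writes `report.json` (all volumes, the seven bin volumes, the config
hash), `curves.csv` (frame time, mean lung RE, background trace) and
`bin_map.nii.gz` (the 0–6 class map). Reading the numbers: on this
reduced 48×48, 2-slice phantom the lung rasterises to 0.87 ml; 48% of it
stays below the RE = 3 threshold after the simulated injection; the
histogram rule finds 0.08 ml of high-baseline-intensity tissue; and the
3000-spoke baseline image has body SNR ≈ 91. Re-running the same config
and seed reproduces the report byte for byte. The same call in R:

```r
library(utedce)
cfg <- pipeline_config(preset = "bleo_d28", seed = 1, matrix_size = 48,
                       n_slices = 2, n_profiles = 6200,
                       time_scale = 0.0667, zero_fill = 1,
                       baseline_spokes = 3000)
report <- run_pipeline(cfg, out_dir = "demo_run")
```

At full scale (`pipeline_config(preset = "bleo_d28",
calibrate_volumes = TRUE)`: matrix 96, 38 slices, ~14 700 profiles over 28
simulated minutes) the presets reproduce the study's geometry — lung
volumes 4.4 → 6.5 ml between control and day-28, with the day-28
low-enhancement fraction exceeding the control's — at a correspondingly
long simulation time.

See `vignettes/utedce-methods.Rmd` for the model, parameter and
numerical-design documentation, including why binning uses raw enhancement
maxima and what the streak-noise floor means for per-pixel class accuracy.

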