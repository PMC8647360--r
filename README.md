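# mintdyn

Quantitative analysis of live-cell imaging of RNA polymerase II Ser2
phosphorylation (RNAP2 Ser2ph) — the transcription-elongation mark — as
visualized by a modification-specific intracellular antibody (mintbody).
The package re-implements, as tested and reusable R code, the image- and
trajectory-analysis chain such studies rely on:

* **Focus quantification** — band-pass spot detection, sub-pixel
  localization, focus size by Gaussian line-profile fitting
  (`Y = a + b·exp(−(x−c)²/(2d²))`, FWHM `= 2√(2 ln 2)·d`), 3D focus
  counting with the divide-by-3 section correction, nuclear/cytoplasmic
  (N/C) ratios, and autothreshold focus-area time courses.
* **Colocalization** — rotation-averaged shifted-Pearson cross-correlation
  functions (CCF) between two channels (Gaussian prefilter, mean
  subtraction within the nucleus mask, x-shifts to ±100 px, averaging over
  0°/90°/180°/270° rotations), and line profiles normalized min–max or
  against the mean nuclear intensity.
* **Single-particle tracking** — 2D Gaussian sub-pixel localization and
  frame-to-frame linking as a linear assignment problem with a 720-nm
  maximum step, no gap closing for single molecules; a separate
  gap-closing tracker (gap ≤ 3 frames, ≥ 30 detections, 200 µm/s speed
  limit) for foci.
* **Motion statistics** — time-averaged MSD; per-trajectory `MSD = 4Dt`
  fits over the first 6 steps; ensemble `MSD = 4Dt^α` fits over 20 steps;
  two-component Gaussian mixture fitting of log₁₀(D) with the bound/mobile
  threshold `D_thr = 10^(μ_fast − 2σ_fast)`; 95% confidence-ellipse
  confinement areas; effective spring coefficients from the regression of
  centripetal displacement on distance from the track's center of mass.
* **Enrichment association** — normalized local-enrichment maps (2-µm
  high-pass, −2SD..+2SD → 0..1), per-trajectory relative intensity
  `I_rel` (mean of the two largest map reads along the track), top/bottom
  quantile classification, Mann–Whitney U comparison, and the
  quantile × D_thr robustness sweep.
* **FRAP** — two-step normalization (background-subtracted bleach/reference
  ratio, then division by the pre-bleach mean) and interpolated
  recovery-time metrics.
* **Synthetic data** — generators with exact ground truth for every stage:
  two-channel focus images with a controllable colocalized fraction,
  fractional Brownian motion trajectories realizing `MSD = 4Dt^α` exactly
  (Cholesky factorization of the fractional Gaussian noise covariance),
  two-population single-molecule movies (Brownian mobile + spring-confined
  bound molecules over an enrichment map), and FRAP curve triplets.

No microscopy data are required anywhere: every analysis runs on simulated
inputs whose true parameters are known, so recovery can be checked
quantitatively.

## Worked example

Simulate foci moving by fractional Brownian motion at the motion
parameters reported for RNAP2 Ser2ph foci (551 ms/frame) and recover them
from the ensemble MSD:

```r
library(mintdyn)

ts  <- simulate_fbm_tracks(D = 0.0029, alpha = 0.69, dt = 0.551,
                           n_steps = 120, n_tracks = 1000, seed = 401)
ens <- ensemble_msd(ts, max_lag = 20)
fit_anomalous(ens, n_lags = 20)
#> DiffusionFit: D = 0.00293 um^2/s, alpha = 0.687 (20 lags)
```

`D` is the generalized diffusion coefficient (µm²/s, strictly µm²/s^α) and
`α < 1` indicates sub-diffusive, constrained motion — the fitted values
match the simulation truth to within the estimator's standard error.

The full workflow lives in `analysis/01…05`; for example
`analysis/04_enrichment_association.R` classifies bound molecules by local
enrichment and prints

```
bound tracks (D <= 0.114): n = 472; top 25% I_rel median D = 0.0158, bottom 25% = 0.0090
Mann-Whitney U = 10216, two-sided p = 5.5e-10
sweep: 72/72 evaluable cells, 72 with positive median-D difference, 72 with p < 0.05
```

i.e. bound molecules inside enrichment regions of the elongation mark are
reported as more mobile than bound molecules outside them (the simulation
injected a 1.5× difference), and the conclusion survives every
quantile/threshold combination of the robustness sweep.

Run the scripts in order from the repository root:

```sh
Rscript analysis/01_foci_characterization.R
Rscript analysis/02_colocalization.R
Rscript analysis/03_single_molecule_mobility.R
Rscript analysis/04_enrichment_association.R
Rscript analysis/05_foci_dynamics_frap.R
```

Each writes its tables under `results/`.

## Vignette

`vignettes/transcription-foci-dynamics.Rmd` documents the models, the
estimators, the parameter choices (with units and defaults), what the
synthetic-data generators do and do not emulate, and the package's known
limitations.
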