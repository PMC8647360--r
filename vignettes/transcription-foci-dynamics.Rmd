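---
title: "Models and methods: transcription-foci dynamics from live-cell imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: transcription-foci dynamics from live-cell imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mintdyn)
```

# Scope

`mintdyn` analyzes live-cell fluorescence imaging of nuclear foci of the
RNAP2 Ser2ph transcription-elongation mark and of single tagged
molecules moving relative to those foci. All analyses operate on either
microscopy stacks (multi-page TIFF) or trajectory tables; because no
public raw recordings exist for this kind of experiment, the package
ships synthetic-data generators with exact ground truth, and every
estimator is validated against them. This vignette explains the models,
the estimators, the defaults, and the limits of what the synthetic tests
demonstrate.

# Foci detection and quantification

**Spot detection.** Candidate foci are local maxima of a
difference-of-Gaussians band-pass matched to the expected spot diameter
(default 7 px, the scale of sub-diffraction foci at 0.065 µm/px). Two
gates follow: the enhanced value must exceed the local mean by
`sd_factor` (default 2) local standard deviations, and the raw contrast
must reach `min_contrast`. The contrast floor exists because a pure
2-SD rule admits a constant false-positive rate on noise-only frames; the
recommended calibration is to run detection on a blank field and set
`min_contrast` just above the largest blank contrast. Sub-pixel positions
come from the 3×3 intensity centroid — deliberately simpler than the
Gaussian fitting used for single molecules, since focus positions feed
area/count statistics rather than nanometre-scale displacement estimates.
Two maxima closer than about one spot radius merge; that behaviour is
documented rather than "fixed", because it is intrinsic to maxima-based
detection.

**3D counting.** A sub-diffraction focus appears in at most three
adjacent 0.2-µm z-sections, so the per-section counts are summed and
divided by 3 (rounded). Foci spanning fewer sections are under-counted by
the same rule; the correction is a convention, not an unbiased estimator,
and `count_foci_3d` exposes the raw per-section counts so the bias can be
inspected.

**Focus size.** A line profile through a focus is fit with
`Y = a + b·exp(−(x − c)²/(2d²))` by Levenberg–Marquardt least squares
(`minpack.lm`), and `FWHM = 2√(2 ln 2)·d`. On noiseless self-model spots
the fit recovers `d` to optimizer tolerance; on pixel-integrated or
interpolated profiles the apparent width carries the usual +1/12 px²
pixelation variance, which matters only below ~2 px widths.

**N/C ratio.** Background-subtracted mean nuclear intensity over
background-subtracted mean cytoplasmic intensity, with the cytoplasmic
mean reconstructed from whole-cell and nuclear regions. The ratio is
reported as nucleus/cytoplasm — the convention under which
nuclear-enriched probes score above 1. (Method descriptions of this
quantity sometimes state the inverse wording; the implementation follows
the convention that matches the name and the reported high values for
nuclear-accumulating probes.)

**Area time course.** Foci are selected per frame by Otsu's threshold
within the nucleus mask and the supra-threshold area is expressed
relative to frame 1. Otsu assumes a bimodal histogram; on a frame whose
foci have vanished it would split the noise, so the threshold is floored
at median + 3 MAD of the within-mask intensities — with the floor, a
focus-free frame reports near-zero area.

# Colocalization

The cross-correlation function (CCF) is the Pearson correlation between
two channels as a function of lateral x-shift. Both channels are first
Gaussian-filtered (σ = 2 px, suppressing pixel-to-pixel sensitivity
variation — the filter parameter of the original tool is ambiguous
between radius and σ; σ is used here and is configurable) and
mean-subtracted within the nucleus mask. Correlation is computed over the
overlap of the masks at each shift, with no wrap-around, for shifts to
±100 px, and reported over ±50 px. The same curve is computed with
channel B rotated by 90°, 180° and 270° about the mask centroid
(nearest-neighbour resampling, exact on square grids) and the four curves
averaged: rotations destroy genuine spatial correspondence while
preserving intensity statistics, so the rotation-averaged curve acts as
an internal randomization control; a colocalized pair keeps a central
peak, an uncorrelated pair flattens. Pearson correlation is invariant to
affine intensity rescaling of either channel, and the tests assert this.

Line profiles average across a configurable thickness perpendicular to
the line (bilinear interpolation) and normalize either min–max (0..1 on
the line) or against the average nuclear intensity after subtracting a
cytoplasmic baseline.

# Single-molecule tracking

**Detection.** Candidates are local maxima of a σ-matched smoothed frame
above a robust noise floor (median + ½·snr_min·MAD); each is refined by
least-squares fitting of a 2D Gaussian with amplitude, position and
offset free and σ fixed at the nominal PSF width (free-σ fitting is
available). Detections with amplitude below `snr_min`× the frame MAD are
discarded. On noiseless spots the localization error is < 0.05 px; at
SNR ≈ 5 the RMSE stays below 0.5 px.

**Linking.** Per consecutive frame pair, a one-to-one assignment
minimizes the total squared displacement among pairs within the 720-nm
maximum step; unassigned detections start or terminate tracks. The
assignment is solved as a maximum-weight bipartite matching (weight
`max_step² − d²`, which is the standard birth/death-cost reduction of the
linear assignment problem). No gap closing and no motion model are used
for single molecules; tracks must have at least 6 displacements
(7 points, 200 ms at 33-ms frames) to be analyzed. The foci tracker adds
gap closing up to 3 missing frames with a 200 µm/s speed limit and keeps
tracks with ≥ 30 detections; gap positions are flagged, never
interpolated.

# Motion statistics

**MSD.** Time-averaged over all overlapping pairs,
`MSD(kΔt) = mean_i |r(i+k) − r(i)|²`; frames missing due to gaps simply
contribute no pairs. The implementation is property-tested against a
brute-force double loop.

**Diffusion fits.** Per-trajectory D uses the first 6 MSD lags with the
zero-intercept model `MSD = 4Dt` (the printed model has no intercept; an
optional offset term for localization error exists but is off by
default — with it off, the localization-error floor inflates per-track D
by ≈ σ²·Σt/Σt², about 0.005 µm²/s at σ = 25 nm and 33-ms frames, a bias
shared by all trajectories and therefore harmless to relative
comparisons). Ensemble anomalous fits use unweighted nonlinear least
squares of `MSD = 4Dt^α` over the first 20 lags, initialized from the
log–log regression, with `D > 0` and `0 < α < 2` enforced.

**Bound/mobile classification.** log₁₀(D) of all trajectories is fit
with a two-component Gaussian mixture and the threshold set at
`D_thr = 10^(μ_fast − 2σ_fast)`, so 97.7% of a Gaussian fast component
remains above threshold. The default route is EM on the raw values
(`mclust`, unequal variances); a histogram least-squares route (bin width
0.1 log units) is retained as a fidelity cross-check and the two agree to
±0.02 log units on well-separated mixtures. When model selection prefers
one component, or a component weight falls below 1%, or a σ degenerates,
the fit falls back to a single Gaussian with a warning rather than
reporting a spurious threshold.

**Confinement.** The confinement area is `π·q·√det Σ` with Σ the sample
covariance of the track's points and `q = qchisq(0.95, 2) = 5.991`; the
ellipse empirically contains 95% ± 1% of points for large stationary
Gaussian tracks.

**Spring coefficient.** For each step, the centripetal component
`c_i = (r_{i+1} − r_i)·(com − r_i)/|r_i − com|` is regressed on the
distance `d_i = |r_i − com|`; the slope divided by Δt is the effective
spring coefficient (1/s, positive = restoring). The sign and per-second
convention are declared here because printed descriptions leave them
open. On discretized mean-reverting tracks the slope recovers the true
relaxation per frame; on free Brownian tracks the estimator has a
positive finite-length bias (the center of mass is estimated from the
same points), so comparisons against zero should always be accompanied by
the bias measured on matched free simulations — the test suite measures
it rather than assuming it away.

# Enrichment association

The enrichment map is the time-averaged mintbody channel, high-pass
filtered by subtracting a Gaussian blur whose σ equals the 2-µm cutoff
(the kernel is unnamed in typical method descriptions; Gaussian
subtraction is chosen for smoothness and separability), then mapped
linearly from mean ± 2 SD (computed within the nucleus mask) to 0..1 with
clipping. The map is invariant to affine rescaling of the input, so
`I_rel` statistics inherit that invariance. Map reads use the nearest
pixel (not interpolation), matching the pixel-count framing of the
frequency statistic; `I_rel` is the mean of the two largest reads along
the trajectory and `freq` the fraction of reads above 0.5. Bound
trajectories are ranked by `I_rel`; the top and bottom 25% (ties broken
by track id for determinism) are compared by two-sided Mann–Whitney U
(exact for small tie-free samples, normal approximation with tie
correction otherwise, and tested against brute-force pair counting). The
robustness sweep re-runs the comparison over quantiles 5–45% and
`D_thr` 0.025–0.169 µm²/s and reports Δmedian D, p, and group sizes per
cell; under-populated cells are reported as missing, not errors.

# FRAP

Two-step normalization: background is subtracted from the bleach-spot and
nuclear-reference series, the ratio is taken per time point (cancelling
acquisition photobleaching exactly when it multiplies both series), and
the result is divided by its pre-bleach mean, making the pre-bleach level
exactly 1. Recovery times interpolate linearly between frames because the
47.8-ms sampling would otherwise quantize the estimate.

# Synthetic data: what it emulates, and what it does not

The generators are first-class, tested code, with fixed defaults chosen
once as the study conditions:

* **fBm trajectories** realize `MSD = 4Dt^α` exactly at every lag by
  Cholesky factorization of the fractional Gaussian increment covariance
  `γ(k) = D·Δt^α(|k+1|^α − 2|k|^α + |k−1|^α)` per axis (this form makes
  the 2D ensemble MSD equal `4Dt^α`; the exactness is what allows
  ± a few percent acceptance bands on recovered parameters). Exact
  synthesis is O(n²); track length is capped at 1024 steps. Acceptance
  simulations use 1,000 tracks of 120 steps at 551 ms/frame — about one
  minute of imaging per focus, within the range of real foci tracking —
  so the 20-lag ensemble-MSD estimator's seed-to-seed spread sits inside
  the ±0.03 band on α.
* **Two-population movies** combine Brownian mobile molecules with bound
  molecules following a discretized mean-reverting (spring) process
  around fixed anchors. Defaults: κ = 2/s and D_bound = 0.008 µm²/s, so
  the stationary confinement radius is ~60–90 nm (typical of
  chromatin-bound proteins) and the *measured* slow log₁₀(D) component
  lands near −1.8, the scale reported for bound nuclear factors once
  localization error is included; D_mobile = 0.5 µm²/s; 33.3 ms/frame;
  0.080 µm/px; peak amplitude 300 photons over background 20 (≈ 25-nm
  localization precision). Enrichment maps for simulations are
  non-overlapping Gaussian blobs of σ = 0.48 µm — the feature scale a
  2-µm high-pass admits — covering ~10% of the field. The end-to-end
  fixtures use sparse fields (20 bound + 10 mobile molecules per 59-µm²
  field) across many movies, mirroring the ultra-low labeling densities
  of real single-molecule imaging; dense fields are avoided because
  overlapping PSFs inside enrichment blobs fragment exactly the
  trajectories of interest. The spring process is a testing stand-in,
  not a claim about the true motion model of bound molecules.
* **Focus image pairs** render pixel-integrated (error-function) Gaussian
  spots in a circular nucleus with Poisson noise on background + signal;
  channel B reuses a `rho` fraction of channel A's positions. EM-gain
  noise, 3D PSFs, photobleaching and blinking are deliberately not
  modelled; the photon model is sufficient to exercise detection and
  correlation logic, not to benchmark camera calibration.
* **FRAP curves** follow a single-exponential recovery with closed form
  `1 − bleach_depth·(1 − mobile_fraction·(1 − e^{−t/τ}))`, multiplied by
  an acquisition-bleaching decay that also multiplies the reference.

Because the generators are idealizations, green tests demonstrate that
the estimators recover the truth *under the stated models* — they do not
certify performance on aberrated PSFs, anisotropic backgrounds, z-drift,
or motion models outside fBm/Brownian/spring.

# Numerical choices and degenerate inputs

Pixel convention: 1-based indices, pixel centers at `(index − 0.5)·pixel
size`, positions in µm everywhere except at I/O boundaries. Gaussian
blurs replicate edges (and pad, so 2-µm kernels work on small nuclei).
Local-maxima ties break lexicographically by (row, col). Mixture-fit
collapse, constant images, degenerate covariances, zero-length lines,
reference ≤ background, and sub-minimal track lengths all raise errors
with specific messages; the sweep reports empty cells as missing. All
generators take explicit seeds and restore the caller's RNG state;
`run_pipeline` writes a manifest with a config hash and per-table MD5s,
and re-running a config reproduces the tables bit-identically.

# Problem sizes

Defaults in the analysis scripts and acceptance checks were sized for a
desktop: 1,000 × 120-step trajectories for ensemble fits, 10⁵ samples for
mixture recovery, 10⁴ points for ellipse coverage, and 40 sparse
60-frame movies (~1,300 trajectories, ~950 bound) for the end-to-end
association analysis — comparable to one replicate of one protein in a
real experiment.

# Known limitations

* The molecule linker is a faithful but simplified reduction of
  full-featured trackers: no Kalman prediction, no merge/split handling
  (intentional for molecules, where those features were explicitly not
  used; a limitation for dense foci fields).
* Anomalous D is reported in µm²/s by convention although its strict unit
  is µm²/s^α.
* The divide-by-3 z-count correction under-counts foci spanning fewer
  than three sections.
* Per-track D from 6 lags without an intercept absorbs localization error
  into D; absolute values are therefore upper bounds, while group
  comparisons are unaffected.
* `compute_ccf` rotations other than multiples of 90° would require
  interpolation and are not offered.
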