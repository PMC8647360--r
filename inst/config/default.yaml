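# Default pipeline parameters. These mirror the standard analysis
# parameterization used throughout the package documentation.
seed: 1
foci:
  typical_diameter_px: 7
  sd_factor: 2
  min_contrast: 0
tracking:
  max_step_um: 0.720
  min_steps: 6
  psf_sigma_px: 1.5
  snr_min: 4
foci_tracking:
  max_gap: 3
  min_length: 30
  max_speed_um_s: 200
motion:
  linear_fit_lags: 6
  anomalous_fit_lags: 20
association:
  quantile: 0.25
enrichment:
  highpass_cutoff_um: 2.0
  k_sd: 2
ccf:
  max_shift_px: 100
  gauss_radius_px: 2
  report_range_px: 50
imaging:
  pixel_size_confocal_um: 0.065
  pixel_size_single_molecule_um: 0.080
  frame_interval_foci_s: 0.551
  frame_interval_single_molecule_s: 0.03333
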