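# Demo configuration: small synthetic cohort with ground truth.
# The phantom's ground-truth biomass fraction is defined on water-excess
# absorbance, so the estimator is run in its matching convention here:
# no displaced-medium compensation and no water-share corrections
# (the phantom declares its water/biomass split explicitly).
cohort:
  fraction: 0.10
  n_cells: 4
  fov_px: 360
  pixel_size_nm: 80
  cell_semi_axes_um: [8.0, 7.0, 2.0]
  n_reference_virions: 5

absorbance:
  medium_compensation: false
  water_correction_cell: 0.0
  water_correction_virion: 0.0

seeds:
  phantom: 101
  titration: 202
  tga: 303
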