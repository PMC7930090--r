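# Default pipeline configuration.  Every physical constant of the analysis
# lives here, none in code.
optics:
  medium_transmission: 0.27      # through medium_thickness_um of medium
  medium_thickness_um: 10.0
  mu_biomass: 1.1                # per um, dry biomass in the water window
  flat_field_photons: 700        # photons/pixel without sample
  ice_thickness_um: 10.0         # medium traversed outside the cell

phantom:
  pixel_size_nm: 19.3
  fov_px: 2048
  cell_semi_axes_um: [15.0, 12.5, 2.0]   # 30 x 25 x 4 um cell
  cell_density: 0.14             # dry-biomass volume fraction (calibrated
                                 # to ~130 photons/pixel in-cell mean)
  virion_length_nm: 1250
  virion_width_nm: 590

classification:
  min_length_nm: 700
  max_length_nm: 1500
  min_ellipticity: 1.3

absorbance:
  smoothing_sigma_px: 1
  water_correction_cell: 0.15    # share of cell absorbance due to water
  water_correction_virion: 0.03
  medium_compensation: true
  displaced_medium_um: 4.0       # typical cell thickness
  background_ring:
    n_points: 36
    offsets_um: [2.0, 3.5, 5.0]
  orientation_count_correction: true

cohort:
  fraction: 0.10                 # target virion share of cell absorbance
  n_cells: 4
  fov_px: 360
  pixel_size_nm: 80
  cell_semi_axes_um: [8.0, 7.0, 2.0]
  n_reference_virions: 5

titration:
  method: ml
  a: 1210                        # infectious units/well at step 0
  wells: 15
  dilutions: ["2^0", "2^-1", "2^-2", "2^-3", "2^-4", "2^-5", "2^-6",
              "2^-7", "2^-8", "2^-9", "2^-10", "2^-11", "2^-12"]
  bookkeeping:
    well0_dilution: 1.0e-6
    inoculum_volume_ml: 0.1
    suspension_volume_ml: 10.0   # 3 ml inoculation + 7 ml medium
    n_cells: 2.0e+6

tga:
  plateau_virus: 0.68
  plateau_cell: 0.28
  noise_sd: 0.002

biomass:
  cell_volume_um3: 3000.0

seeds:
  phantom: 101
  titration: 202
  tga: 303

output:
  write_images: false
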