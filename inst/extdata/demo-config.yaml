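# Demo configuration: the reference 25 keV grating interferometer with a
# small fetus phantom.  Any omitted key falls back to the package default.
instrument:
  energy_keV: 25
  wavelength_rounding: "3sf"
  g2:
    tilt_deg: 45
  detector:
    effective_pixel_um: 15.5
scan:
  n_projections: 600
  n_steps: 5
  exposure_s: 0.5
  flat_interval_deg: 36
phantom:
  scenario: fetus_fresh
  grid_n: 48
  voxel_size_mm: 0.1
simulation:
  photon_budget: .inf
  visibility: 0.3
  n_angles: 120
seed: 1
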