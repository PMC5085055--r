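# Example run configuration: mid-stiffness hydrogel phantom, 450 um
geometry:
  posterior_radius: 8.60   # mm
  thickness: 0.45          # mm (anterior radius derived: 9.05 mm)
  aperture_radius: 5.5     # mm, holder clamp opening
iop_mmhg: 15
material:                  # Mooney-Rivlin constants, MPa
  c10: 0.0375
  c01: 0.0125
airpuff:
  peak_pressure_mpa: 0.0045
  spatial_sigma_mm: 1.5
  duration_ms: 30
  n_frames: 140
solver:
  n_through_thickness: 4
  n_meridian: 100
  tol: 1.0e-6
noise:
  displacement_sigma_mm: 0.010
  stress_sigma_rel: 0.02
seed: 1
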