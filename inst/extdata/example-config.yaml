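# chambergrow run configuration. All lengths in meters (must be integer
# multiples of model.spacing), forces in newtons, strain thresholds in
# microstrain. Any omitted entry falls back to the package default.
model:
  spacing: 5.0e-5              # voxel edge (50 um)
  block_size: [2.4e-3, 2.4e-3, 2.8e-3]   # bone block x, y, z
  abutment_height: 8.0e-4      # implant protrusion above the crest
  cortical_thickness: 3.0e-4   # cortical crest layer
  core_radius: 4.5e-4
  implant_length: 2.0e-3       # embedded length, tip to crest
  thread_pitch: 6.0e-4
  thread_depth: 1.5e-4         # radial protrusion of a thread ring
  thread_height: 1.0e-4        # axial extent of a thread ring
  trough_depth: 3.0e-4         # healing-chamber depth (default pitch / 2)
  roi_margin: 5.0e-4           # ROI shell beyond the outer thread radius

materials:                     # isotropic linear elasticity per phase
  CANCELLOUS: {young_modulus: 6.9e+8,  poisson_ratio: 0.30}
  CORTICAL:   {young_modulus: 1.37e+10, poisson_ratio: 0.30}
  IMPLANT:    {young_modulus: 1.10e+11, poisson_ratio: 0.35}  # Ti6Al4V

load:
  axial_force: 3.0             # compressive, along -z on the abutment top

remodeling:
  eps_du: 100                  # disuse threshold
  eps_pl: 400                  # physiological window, lower
  eps_pu: 1500                 # physiological window, upper
  eps_ol: 3000                 # overuse threshold
  sensing_radius: 1.5e-4       # stress-sensing neighbourhood
  gamma_scale: 1.0             # nonuniformity saturation scale
  n_act: 1                     # decision sweeps per FE solve
  seed: 1
  decision_mode: stochastic

evaluation:
  healthy_low: 400             # healthy-bone strain window (inclusive)
  healthy_high: 1500
  denominator: bone_in_roi

run:
  max_iter: 15
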