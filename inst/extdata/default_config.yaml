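# Default study configuration and model constants.
# Values here mirror the package defaults; edit a copy and pass it to the
# command-line driver or read_study_config().

study:
  cohort: fixture          # fixture | synthetic
  n: 4
  seed: 1
  arm: mri                 # mri | rigid | eptfe16
  met_levels: [1, 3, 5]
  stenosis_levels: []      # fractions in (0, 1); e.g. [0.1, 0.3, 0.5, 0.7, 0.9]
  tol: 1.0e-3              # periodicity tolerance on cycle-mean pressures
  out_dir: null

fluid:
  density: 1.06            # g/cm3
  viscosity: 0.04          # poise

oxygen:
  hb: 13.26                # g/dL
  o2_capacity: 1.34        # mL O2 per g hemoglobin
  sa_o2: 0.94
  po2_arterial: 90         # mmHg
  po2_venous: 40           # mmHg
  basal_vo2: 6.5           # mL/kg/min
  dissolved_oer: 0.003
  dissolved_svo2: 0.03

graft:
  wall_thickness: 1.5      # mm
  graft_length: 50         # mm
  stenosis_length: 20      # mm
  kv: 40.7437              # viscous loss coefficient (128/pi)
  kt: 1.52                 # expansion loss coefficient

exercise:
  hr_max: 190              # beats/min at MET 5
  pvr_slope: 0.05          # pulmonary resistance reduction per MET above rest
  contractility_slope: 0.25
  venoconstriction_slope: 0.07
  tvr_floor_frac: 0.1

compensation:
  target: max_aortic_pressure
  tol_mmhg: 0.5
  bracket: [0.5, 3.0]
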