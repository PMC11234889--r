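# Default exposure-factor distributions (PLACEHOLDER values).
#
# These are plausible, literature-style magnitudes for demonstration and
# testing only — they are NOT authoritative study-derived distributions.
# Replace with fitted distributions for any real assessment.
#
# Lognormal factors are parameterized by geometric mean (gm) and geometric
# standard deviation (gsd). `support` gives truncation bounds; sampling is
# by rejection.

surface_dust_loading:        # indoor surface/object dust loading
  kind: lognormal
  gm: 0.005                  # mg/cm2
  gsd: 3.0
  units: mg/cm2
  support: [0.0, .inf]

soil_loading_outdoor:        # outdoor surface soil loading
  kind: lognormal
  gm: 0.05
  gsd: 3.0
  units: mg/cm2
  support: [0.0, .inf]

transfer_fraction:           # fraction of loading difference moved per contact
  kind: uniform
  min: 0.1
  max: 0.4
  units: unitless
  support: [0.0, 1.0]

fraction_hand_contact:       # fraction of hand surface touching per contact
  kind: uniform
  min: 0.1
  max: 0.3
  units: unitless
  support: [0.0, 1.0]

hand_area:                   # one palmar hand, per child
  kind: lognormal
  gm: 150.0
  gsd: 1.3
  units: cm2
  support: [50.0, 400.0]

mouthed_area:                # area mouthed per event
  kind: triangular
  min: 1.0
  mode: 10.0
  max: 20.0
  units: cm2
  support: [0.0, 50.0]

mouthing_removal_efficiency: # fraction of loading on mouthed area ingested
  kind: uniform
  min: 0.3
  max: 0.7
  units: unitless
  support: [0.0, 1.0]

max_hand_loading:            # saturation cap on hand loading, per child
  kind: point
  value: 0.5
  units: mg/cm2
  support: [0.0, .inf]

handwash_removal_efficiency:
  kind: uniform
  min: 0.5
  max: 0.95
  units: unitless
  support: [0.0, 1.0]

body_weight:                 # per child
  kind: lognormal
  gm: 12.0
  gsd: 1.3
  units: kg
  support: [4.0, 40.0]

contaminant_concentration:   # contaminant in dust/soil
  kind: point
  value: 100.0
  units: mg/kg
  support: [0.0, .inf]

exposure_factor:             # pass-through multiplier in the dose algorithms
  kind: point
  value: 1.0
  units: unitless
  support: [0.0, 1.0]

absorption_fraction:         # dermal absorption factor
  kind: point
  value: 0.1
  units: unitless
  support: [0.0, 1.0]

soil_skin_adherence:
  kind: lognormal
  gm: 0.2
  gsd: 2.0
  units: mg/cm2
  support: [0.0, .inf]

surface_area_contact:        # surface area available per contact event
  kind: triangular
  min: 5.0
  mode: 10.0
  max: 20.0
  units: cm2
  support: [0.0, 100.0]

# Optional per-object overrides of the surface loading distribution.
surface_loading_by_object:
  Pacifier:
    kind: lognormal
    gm: 0.001
    gsd: 2.0
    units: mg/cm2
    support: [0.0, .inf]
  Floor:
    kind: lognormal
    gm: 0.01
    gsd: 3.0
    units: mg/cm2
    support: [0.0, .inf]
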