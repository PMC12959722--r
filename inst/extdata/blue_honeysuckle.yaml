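# Field-measured parameters of Blue Honeysuckle (Lonicera caerulea L.),
# 5-8 year old plants. Each entry carries the sample mean, the sample
# standard deviation, and an explicit unit string. All values convert to
# SI internally.
branch_density:
  mean: 887
  sd: 46
  unit: kg/m^3
branch_modulus:
  mean: 5023
  sd: 643
  unit: MPa
allowable_stress:
  mean: 35.3
  sd: 13.7
  unit: MPa
branch_length:
  mean: 885
  sd: 171
  unit: mm
branch_basal_diameter:
  mean: 9.3
  sd: 2.4
  unit: mm
branch_apical_diameter:
  mean: 2.9
  sd: 0.6
  unit: mm
stem_length:
  mean: 7.3
  sd: 2.1
  unit: mm
stem_diameter:
  mean: 0.53
  sd: 0.13
  unit: mm
fruit_mass:
  mean: 0.86
  sd: 0.26
  unit: g
fruit_length:
  mean: 18.21
  sd: 5.53
  unit: mm
fruit_width:
  mean: 7.68
  sd: 2.45
  unit: mm
fruit_bulk_density:
  mean: 1280
  sd: 167
  unit: kg/m^3
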