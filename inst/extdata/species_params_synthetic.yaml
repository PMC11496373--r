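# SYNTHETIC default top-height-equation constants.
#
# These values are a calibration constructed for this package: they produce
# monotone sigmoid top-height curves of realistic shape for boreal conifers
# (seedling-scale heights at total age 1, half-height in the second or third
# decade, site index recovered exactly at total age 50). They are NOT the
# published operational constants of any growth-and-yield system; supply your
# own parameter file for operational use.
#
# Schema: one entry per species code with `constants` (4 numbers, equation
# order) and `common_age` (years). The equation form is implied by the
# species code (see ?species_params).
white_spruce:
  constants: [9.66, -4.0, -0.05, 0.1]
  common_age: 16
lodgepole_pine:
  constants: [15.45, -9.0, -0.15, 0.1]
  common_age: 32
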