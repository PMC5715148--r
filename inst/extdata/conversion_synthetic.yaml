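# SYNTHETIC placeholder tissue-to-epidermis conversion coefficients.
#
# These are NOT the regression equations established for real loggerhead
# tissues; they exist so the simulator and examples run self-contained.
# Analyses of real data must replace this file with the published
# coefficients for their study system (see ?conversionModel).
epidermis:
  slopeC: 1.0
  interceptC: 0.0
  slopeN: 1.0
  interceptN: 0.0
unhatched_egg:
  slopeC: 0.95
  interceptC: 0.50
  slopeN: 0.98
  interceptN: 0.80
red_blood_cells:
  slopeC: 1.00
  interceptC: 1.20
  slopeN: 1.00
  interceptN: 0.60
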