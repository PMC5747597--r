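# A grossly miscalibrated test device: constant +20 mm Hg bias on both
# pressures (+10 bpm on heart rate). Every selected difference lands
# beyond the last band, so phase 1 must fail.
n_subjects: 125
seed: 20102
dropout: 0.2
integer_rounding: true
variables:
  SBP:
    test_bias: 20
  DBP:
    test_bias: 20
  HR:
    test_bias: 10
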