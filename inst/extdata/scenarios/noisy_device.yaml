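# A borderline device: moderate constant bias (6 mm Hg / 4 bpm) with
# inflated device noise (4 units SD). Sits near the decision boundary,
# failing more often than it passes.
n_subjects: 125
seed: 20103
dropout: 0.2
integer_rounding: true
variables:
  SBP:
    test_bias: 6
    test_noise_sd: 4
  DBP:
    test_bias: 6
    test_noise_sd: 4
  HR:
    test_bias: 4
    test_noise_sd: 3
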