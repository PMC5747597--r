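# Zero-bias low-noise scenario calibrated to a published passing
# validation study: 125 recruits, 20% loss to follow-up (100
# completers), serial SDs chosen so the selected-difference
# distribution reproduces the study's printed band proportions
# (about 83% / 91% / 90% of SBP / DBP / HR differences in band 1).
n_subjects: 125
seed: 20101
dropout: 0.2
integer_rounding: true
variables:
  SBP:
    within_subject_sd: 4.0
  DBP:
    within_subject_sd: 3.0
  HR:
    within_subject_sd: 1.7
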