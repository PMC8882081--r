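# Metformin + dasatinib, scenario 2: tenfold lower Ki for OCT2 and MATEs
# simultaneously (0.0034 / 0.022 uM).
label: "metformin + dasatinib, tenfold lower Ki"
victim: metformin
perpetrator: dasatinib
victim_dose: 500
perp_dose: 100
perp_n_doses: 6
perp_interval: 24
co_dose_time: 96
window: 36
n_subjects: 10
n_trials: 10
seed: 20260925
ki_fold:
  OCT2: 10
  MATE: 10
site_oct2: plasma
site_mate: kidney
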