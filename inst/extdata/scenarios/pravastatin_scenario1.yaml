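# Pravastatin + dasatinib: reported in vitro Ki (OATP1B1 2.4 uM,
# OATP1B3 2.88 uM); pravastatin 40 mg single oral dose co-dosed with the
# day-5 dose of dasatinib 100 mg QD.
label: "pravastatin + dasatinib, reported Ki"
victim: pravastatin
perpetrator: dasatinib
victim_dose: 40
perp_dose: 100
perp_n_doses: 6
perp_interval: 24
co_dose_time: 96
window: 36
n_subjects: 10
n_trials: 10
seed: 20260925
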