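# Metformin + dasatinib, scenario 1: measured in vitro Ki
# (OCT2 0.034 uM, MATE 0.22 uM). 10 trials x 10 subjects, paired
# crossover; metformin 500 mg single oral dose co-dosed with the day-5
# dose of dasatinib 100 mg QD.
label: "metformin + dasatinib, measured Ki"
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
site_oct2: plasma
site_mate: kidney
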