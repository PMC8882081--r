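# Reference-human physiology for the perfusion-limited PBPK model.
# Volumes (L) and regional blood flows (L/h, whole blood) compiled from
# ICRP Publication 89 reference-adult anatomy and Davies & Morris (1993,
# Pharm Res 10:1093) physiological parameter tables, lightly rounded.
# Enzyme-scaling constants from standard IVIVE sources:
#   CYP3A4 hepatic abundance 137 pmol/mg microsomal protein
#     (Rodrigues 1999; Simcyp-class default)
#   MPPGL 40 mg microsomal protein / g liver (Barter et al. 2007)
#   liver weight 1650 g (Davies & Morris 1993)
#   CYP3A4 turnover kdeg 0.019 1/h (t1/2 ~36 h; Yang et al. 2008)
# GFR 7.2 L/h (120 mL/min). Q_gut 18 L/h: villous-flow-limited effective
# flow of the intestinal first-pass model (Yang et al. 2007, Curr Drug
# Metab 8:676 report ~18 L/h for a reference adult).
schema_version: 1
body_weight: 70.0       # kg
hct: 0.45
gfr: 7.2                # L/h
cyp3a4_abundance: 137.0 # pmol/mg microsomal protein
mppgl: 40.0             # mg microsomal protein per g liver
liver_weight: 1650.0    # g
kdeg_cyp3a4: 0.019      # 1/h
q_gut: 18.0             # L/h
volumes:                # L
  adipose: 18.2
  bone: 10.5
  brain: 1.45
  gut: 1.65
  heart: 0.33
  kidney: 0.31
  liver: 1.80
  lung: 0.53
  muscle: 29.0
  skin: 3.30
  spleen: 0.15
  arterial: 1.70
  venous: 3.90
  portal: 0.70
flows:                  # L/h whole blood; lung carries cardiac output
  adipose: 19.5
  bone: 11.7
  brain: 46.8
  gut: 58.5
  heart: 15.6
  kidney: 74.1
  muscle: 55.0
  skin: 19.5
  spleen: 11.7
  hepatic_artery: 25.0
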