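# Tissue composition for mechanistic tissue:plasma partition prediction,
# compiled from the Rodgers & Rowland tissue-composition method papers
# (J Pharm Sci 2005 94:1259; J Pharm Sci 2006 95:1238; Pharm Res 2007
# 24:918). Fractional volumes of extracellular water (f_ew), intracellular
# water (f_iw), neutral lipid (f_nl) and neutral phospholipid (f_npl) are
# per mL tissue; acidic phospholipid (ap) in mg/g tissue. protein_ratio is
# the tissue:plasma ratio of the binding protein used for the
# neutral/acid/weak-base route.
schema_version: 1
ph:
  plasma: 7.4
  intracellular: 7.0
  blood_cells: 7.22
plasma:
  f_nl: 0.0023
  f_npl: 0.0013
blood_cells:
  f_iw: 0.603
  f_nl: 0.0017
  f_npl: 0.0029
  ap: 0.5
tissues:
  adipose:  {f_ew: 0.135, f_iw: 0.017, f_nl: 0.853,  f_npl: 0.0016, ap: 0.40, protein_ratio: 0.049}
  bone:     {f_ew: 0.100, f_iw: 0.346, f_nl: 0.017,  f_npl: 0.0017, ap: 0.67, protein_ratio: 0.100}
  brain:    {f_ew: 0.162, f_iw: 0.620, f_nl: 0.039,  f_npl: 0.0015, ap: 0.40, protein_ratio: 0.048}
  gut:      {f_ew: 0.282, f_iw: 0.475, f_nl: 0.038,  f_npl: 0.0125, ap: 2.41, protein_ratio: 0.158}
  heart:    {f_ew: 0.320, f_iw: 0.456, f_nl: 0.014,  f_npl: 0.0111, ap: 2.25, protein_ratio: 0.157}
  kidney:   {f_ew: 0.273, f_iw: 0.483, f_nl: 0.012,  f_npl: 0.0240, ap: 5.03, protein_ratio: 0.130}
  liver:    {f_ew: 0.161, f_iw: 0.573, f_nl: 0.014,  f_npl: 0.0240, ap: 4.56, protein_ratio: 0.086}
  lung:     {f_ew: 0.336, f_iw: 0.446, f_nl: 0.022,  f_npl: 0.0128, ap: 3.91, protein_ratio: 0.212}
  muscle:   {f_ew: 0.118, f_iw: 0.630, f_nl: 0.010,  f_npl: 0.0072, ap: 2.42, protein_ratio: 0.064}
  skin:     {f_ew: 0.382, f_iw: 0.291, f_nl: 0.060,  f_npl: 0.0044, ap: 1.32, protein_ratio: 0.277}
  spleen:   {f_ew: 0.207, f_iw: 0.579, f_nl: 0.0077, f_npl: 0.0113, ap: 3.18, protein_ratio: 0.097}
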