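# Synthetic, literature-informed GTPase-cycle constants per KRAS line.
# Units 1/min; Kd_raf in relative concentration units (wild type = 1).
# Mutants are GAP-insensitive (k_gap = 0) with total hydrolysis reduced
# ~84x (G12C), ~250x (G12D), ~500x (G12V) and ~800x (Q61R) versus wild type,
# and RAF affinity weakened by at most 7-fold, consistent with published
# relative bounds from in vitro biochemical assays. These are stand-in values
# for demonstration and testing, not measured constants.
KRAS_WT:
  k_int: 0.018
  k_gap: 5.0
  k_ex_basal: 0.01
  k_ex_stim: 0.25
  Kd_raf: 1.0
  provenance: synthetic (wild-type reference)
KRAS_G12C:
  k_int: 0.06
  k_gap: 0.0
  k_ex_basal: 0.01
  k_ex_stim: 0.25
  Kd_raf: 2.3
  provenance: synthetic (GAP-insensitive, ~84x reduced hydrolysis)
KRAS_G12D:
  k_int: 0.02
  k_gap: 0.0
  k_ex_basal: 0.01
  k_ex_stim: 0.25
  Kd_raf: 1.9
  provenance: synthetic (GAP-insensitive, ~250x reduced hydrolysis)
KRAS_G12V:
  k_int: 0.01
  k_gap: 0.0
  k_ex_basal: 0.01
  k_ex_stim: 0.25
  Kd_raf: 3.1
  provenance: synthetic (GAP-insensitive, ~500x reduced hydrolysis)
KRAS_Q61R:
  k_int: 0.0063
  k_gap: 0.0
  k_ex_basal: 0.01
  k_ex_stim: 0.25
  Kd_raf: 7.0
  provenance: synthetic (GAP-insensitive, ~800x reduced hydrolysis)
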