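# Composite push-pull constants for the MEK and ERK tiers (1/min scale),
# chosen so the wild-type line sits at a few percent fractional ppERK at
# baseline and ~25% at peak stimulation (inside the observed non-saturating
# 1-30% range). Synthetic demonstration values.
a_mek: 50
d_mek: 0.5
a_erk: 0.5
d_erk: 1
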