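# ART-form example scenario: near-field source with local control and
# strong dilution, far-field contribution, half-mask RPE.
E_nf: 10
H_nf: 3
LC_nf: 0.3
P_nf: 1
Su_nf: 0
D_nf: 3
E_ff: 10
H_ff: 3
LC_ff: 1
Seg_ff: 1
Su_ff: 0
D_ff: 0.3
Sep_ff: 1
RPE: 0.1
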