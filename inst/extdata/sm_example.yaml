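# STOFFENMANAGER-form example scenario: dusty powder transfer with
# moderate general ventilation in both zones and a weak background source.
E: 10
H: 3
eta_lcnf: 1
eta_gvnf: 0.3
eta_lcff: 1
eta_gvff: 0.3
a: 0.1
eta_imm: 1
t_h: 1
f_h: 1
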