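# Two-compartment example: 30 m3 workroom, 1 m3 breathing-zone near field,
# constant 10 mg/min source, 1 m3/min general ventilation, 5 m3/min
# inter-zonal air exchange. Steady state: C_ff = 10, C_nf = 12 mg m-3.
V_nf: 1
V_ff: 29
Q: 1
beta: 5
G: 10
t_end: 240
dt: 1
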