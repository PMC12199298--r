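# Qo-site proton-wire nodes. Donors are the quinol-head oxygens; release
# groups discharge the transported proton (H152 via Rieske-domain motion,
# PRA_bL and D278 toward bulk solvent).
name	role
QO1	donor
QO4	donor
Y147	relay
E295	relay
Y297	relay
H276	relay
H152	release
PRA_bL	release
D278	release
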