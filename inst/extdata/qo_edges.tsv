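# Curated Qo-site contact edges: one row per (pair, mechanism).
# mechanism: direct | 1w | 2w (one- / two-water bridge, both heavy-atom
# distances < 0.35 nm). occupancy: fraction of simulated time formed,
# where quantified; NA for edges admitted on free-energy/contact evidence
# without a single quoted occupancy. evidence: md-free-energy (distance
# free-energy landscape), md-contact (direct-contact trajectory),
# md-bridge (water-bridge trajectory).
# Excluded by curation: QO1-PRA_bL (only a three-water bridge: two-water
# rule), QO1-E295 (direct or bridged contact not or very rarely formed),
# Y147-H276 (no contact observed).
a	b	mechanism	occupancy	evidence
QO4	H152	direct	NA	md-free-energy
QO4	H152	1w	NA	md-bridge
QO1	Y147	direct	NA	md-free-energy
QO1	Y147	1w	NA	md-bridge
Y147	E295	direct	NA	md-contact
Y147	E295	1w	NA	md-bridge
Y147	Y297	direct	NA	md-contact
E295	PRA_bL	1w	NA	md-bridge
Y297	PRA_bL	1w	0.16	md-bridge
Y147	PRA_bL	2w	NA	md-bridge
E295	H276	direct	NA	md-contact
H276	D278	direct	NA	md-contact
H276	D278	1w	NA	md-bridge
H276	D278	2w	NA	md-bridge
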