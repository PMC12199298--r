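# Demo pipeline config: synthetic survey ensemble, telegraph contact
# statistics, a metadynamics-reweighted torsional free-energy profile and
# the curated proton-wire enumeration.
stages: [survey, contacts, fes, wires]
seed: 1
out_dir: qowire_demo
n_samples: 5000
n_frames: 20000
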