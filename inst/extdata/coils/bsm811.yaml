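name: BSM-811
inner_radius: 0.044
outer_radius: 0.044
n_windings: 1
n_layers: 1
wing_gap: 0.002
segments_per_wing: 92
integration_step: 2.5e-05
distribution_factor: 7
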