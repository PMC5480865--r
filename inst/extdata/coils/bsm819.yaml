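name: BSM-819
inner_radius: 0.026
outer_radius: 0.044
n_windings: 9
n_layers: 1
wing_gap: 0.002
segments_per_wing: 763
integration_step: 1.2e-05
distribution_factor: 1
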