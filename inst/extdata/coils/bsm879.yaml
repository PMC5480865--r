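name: BSM-879
inner_radius: 0.026
outer_radius: 0.044
n_windings: 9
n_layers: 7
wing_gap: 0.002
segments_per_wing: 5341
integration_step: 4.0e-05
distribution_factor: 1/7
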