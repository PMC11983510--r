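# Example plain-text configuration: any agent_config() key is valid.
epsilon: 0.1
n_planning: 10
gamma: 0.9
lr_mf: 0.1
lr_mb: 0.4
omega: 0.2
sim_start: s0
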