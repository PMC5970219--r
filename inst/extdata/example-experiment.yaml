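# Example experiment configuration: a small single-channel population.
# Every key of experiment_config() can appear here; the params block holds
# model_params() overrides (defaults are the published constants).
condition: single_channel
n_cells: 10
master_seed: 7
out_dir: onoffrf-output
params:
  n_steps_pre: 20000
  n_steps_sound: 20000
  t_adult: 20000
snapshot_steps: [0, 1500, 20000]
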