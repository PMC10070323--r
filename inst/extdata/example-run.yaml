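# Example pipeline configuration for `fndmc run --config ...`
system:
  name: He
trial:
  name: he_pade
  params:
    b: 0.35
vmc:
  n_walkers: 500
  n_steps: 400
dmc:
  tau: 0.01
  n_steps: 1000
  n_walkers: 500
stages: [vmc, dmc]
output_dir: he-run
seed: 1
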