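# Demo pipeline configuration: a cohort-sequential simulation with linear
# development (0.08 Z/year), front-loaded learning increments that are
# larger at younger ages, and the full analysis chain.
simulation:
  n_subjects: 319
  n_visits: 4
  dev_slope: 0.08
  learning_increments: [0.4, 0.15, 0.05]
  learning_age_gradient: -0.04
  noise_sd: 0.5
  re_sd: 0.4
values: [value]
steps: [learning, adjust, develop, triptych]
alpha: 0.05
m: 8
convention: equation
seed: 1
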