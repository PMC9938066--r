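# npodrl run configuration (schema version 1)
#
# Units are fixed by convention: time in hours, amounts in mg, volumes in
# litres, concentrations in mg/L.
version: 1
output_dir: "runs"
# dataset: "runs/dataset.csv"   # required by fit / train / rollout

model:
  # assay SD polynomial sigma(y) = c0 + c1*y + c2*y^2 + c3*y^3
  error: {c0: 0.1, c1: 0.1, c2: 0.0, c3: 0.0}

estimator:
  backend: npod          # "npod" (real fit) or "mock" (fast pseudo-likelihood)
  n_sobol: 51            # Sobol initial support points
  tol: 1.0e-4            # log-likelihood convergence tolerance per cycle
  max_cycles: 100
  weight_floor: 1.0e-6
  merge_tol: 1.0e-4
  nm_maxeval: 200        # Nelder-Mead budget per support point

# optional: explicit model/bounds for the 'fit' command; otherwise the
# environment's starting model and bounds are used
fit:
  model_kind: ~
  bounds: ~

environment:
  model_start: 2
  horizon: 30            # actions per episode
  abort_penalty: -20000
  initial_bounds:        # deliberately misplaced starting search space
    "1": {ke: [0.001, 2.0], v: [125.0, 625.0]}
    "2": {ke: [0.001, 2.0], v: [125.0, 625.0], kcp: [0.001, 10.0], kpc: [10.0, 100.0]}

agent:
  alpha: 0.9             # learning rate
  gamma: 1.0             # discount factor
  episodes: 1000
  seed: 1                # epsilon follows 1/episode

simulate:                # synthetic one-compartment test population
  n_subjects: 20
  model_kind: 1
  seed: 42
  outlier_fraction: 0.05
  conc_floor: 0.0
  doses:
    - {start_time: 0.0, amount: 600.0, duration: 1.0}
  obs_times: [1, 2, 4, 6, 8, 12, 24]
  parameters:
    ke: {means: [0.25, 0.7], sds: [0.05, 0.05], fractions: [0.5, 0.5], range: [0.0, 1.0]}
    v: {means: [120.0], sds: [25.0], fractions: [1.0], range: [50.0, 200.0]}
  outlier_parameters:
    ke: {means: [0.95], sds: [0.02], fractions: [1.0], range: [0.0, 1.0]}
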