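# Small synthetic demonstration scenario: an air-puff-task agent governed by
# the full P-S-F model, compared against its nested S-F variant, then probed
# with a reward-value perturbation emulating an inactivation session.
task: air_puff
agent:
  model: P-S-F
  alpha_l: 0.35
  alpha_f: 0.1
  kappa_r: 2
  kappa_p: 5
  psi: 0.5
scenario:
  n_sessions: 2
  trials_per_session: 250
models: [S-F, P-S-F]
fitting:
  n_restarts: 40
simulation:
  n_reps: 200
perturbation:
  perturbed:
    kappa_r: 6
  n_reps: 100
  mode: carryover
seed: 20260925
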