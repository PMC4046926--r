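schema: forgetsim-config/1
env:
  a_rn: 0.04
  a_nr: 0.08
  a_np: 0.08
  a_pn: 0.04
  reward_pos: 1
  reward_neg: -1
costs:
  scale: 0.1
dp:
  horizon: 5
  gamma: 0.95
lp:
  lattice_spacing: 0.05
  n_cost_bins: 11
extended:
  q_sf: 0.001
  q_fs: 0.001
  time_refinement: 10
  fast_factor: 10
experiment:
  n_agents: 2000
  max_delay: 200
  n_delays: 21
  protocol: single_aversive
  policy: greedy
  free_run_steps: 1000
  free_run_n: 40
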