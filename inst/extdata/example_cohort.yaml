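# Example synthetic cohort specification.
#
# Each group draws ages uniformly from age_range (months). Profile entries
# are either constants or linear age responses {base, per_month, ref_age}:
# value = base + per_month * (age - ref_age), clipped to [0, 1] for
# probabilities. Omitted parameters use strategy_profile() defaults.
seed: 20260925
groups:
- label: single_step        # direct sharers: deliveries go straight to plates
  n_participants: 10
  age_range: [30, 72]
  profile:
    n_cycles: 12
    p_stack: 0.05
    offtask_rate: {base: 2.0, per_month: -0.02, ref_age: 30}
- label: two_step           # stack-then-redistribute sharers
  n_participants: 10
  age_range: [30, 72]
  severity_probs: [0.4, 0.5, 0.1]
  profile:
    n_cycles: 12
    p_stack: {base: 0.3, per_month: 0.008, ref_age: 30}
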