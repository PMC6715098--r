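# Demo simulation scenario: a small cohort of virtual participants running
# complete 30-session training modules against a simulated normative cohort.
n_participants: 3
cohort_n: 100
seed: 1
traits:
  ability_sd: 1.0
  learning_rate: 0.02
  noise_sd: 0.5
  overlong_prob: 0.02
  lapse_prob: 0.05
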