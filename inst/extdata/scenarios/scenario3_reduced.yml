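# Reduced-scale variant of scenario3: one small community, 3 homogeneous
# groups, full 45-cell interaction grid at low trajectory counts.
name: scenario3_reduced
richness: [30]
size: [1000]
distribution: [lognormal]
replicates: 1
dilution_factors: [0.1]
n_trajectories: 10
n_cycles: 30
growth_rate: 0.01
fixation_thresholds: [0.5]
success_threshold: 0.95
groups:
  - {n_groups: 3, niche_mode: homogeneous}
interactions:
  sign_mode: [positive, negative, both]
  strength: [1, 0.1, 0.01, 0.001, 0.0001]
  frequency: [0.01, 0.1, 1.0]
seed: 3
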