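# Study design 3: inter-group interactions. One log-normal community
# (richness 100, size 10^4) at the mildest dilution (0.1); 3 homogeneous or
# 10 heterogeneous groups; interaction grid of 3 signs x 5 strengths x 3
# frequencies; a fresh random unidirectional matrix per trajectory.
name: scenario3
richness: [100]
size: [10000]
distribution: [lognormal]
replicates: 1
dilution_factors: [0.1]
n_trajectories: 100
n_cycles: 200
growth_rate: 0.01
fixation_thresholds: [0.5]
success_threshold: 0.95
groups:
  - {n_groups: 3, niche_mode: homogeneous}
  - {n_groups: 10, niche_mode: heterogeneous}
interactions:
  sign_mode: [positive, negative, both]
  strength: [1, 0.1, 0.01, 0.001, 0.0001]
  frequency: [0.01, 0.1, 1.0]
seed: 3
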