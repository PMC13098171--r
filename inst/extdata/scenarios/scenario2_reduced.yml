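# Reduced-scale variant of scenario2 for quick runs and continuous testing.
name: scenario2_reduced
richness: [30]
size: [1000]
distribution: [lognormal]
replicates: 2
dilution_factors: [0.01, 0.1]
n_trajectories: 20
n_cycles: 60
growth_rate: 0.01
fixation_thresholds: [0.5]
success_threshold: 0.95
groups:
  - {n_groups: 3, niche_mode: homogeneous}
seed: 2
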