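# Reduced-scale variant of scenario1 for quick runs and continuous testing.
name: scenario1_reduced
richness: [10]
size: [1000]
distribution: [uniform]
replicates: 3
dilution_factors: [0.01, 0.05, 0.1]
n_trajectories: 50
n_cycles: 100
growth_rate: 0.01
fixation_thresholds: [0.5]
success_threshold: 0.95
seed: 1
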