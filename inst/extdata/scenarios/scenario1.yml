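# Study design 1: single-group communities, full parameter sweep.
# 3 richness x 2 sizes x 2 distributions = 12 combinations, 30 replicate
# communities each (360 communities), 14 dilution factors (5040
# experiments), 100 trajectories per experiment (504000 trajectories).
name: scenario1
richness: [10, 100, 1000]
size: [10000, 1000000]
distribution: [uniform, lognormal]
replicates: 30
dilution_factors: [0.00025, 0.0004, 0.0005, 0.001, 0.0025, 0.004, 0.005,
                   0.008, 0.01, 0.025, 0.04, 0.05, 0.1, 0.25]
n_trajectories: 100
n_cycles: 200
growth_rate: 0.01
fixation_thresholds: [0.5, 0.9]
success_threshold: 0.95
seed: 1
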