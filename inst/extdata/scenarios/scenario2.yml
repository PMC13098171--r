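# Study design 2: functional groups with fixed carrying capacities.
# Size 10^4, log-normal abundances, richness 100 or 1000 (60 communities),
# nine dilution factors, four group configurations (3 or 10 groups x
# homogeneous or heterogeneous niche sizes).
name: scenario2
richness: [100, 1000]
size: [10000]
distribution: [lognormal]
replicates: 30
dilution_factors: [0.00025, 0.0005, 0.001, 0.0025, 0.005, 0.01, 0.025,
                   0.05, 0.1]
n_trajectories: 100
n_cycles: 200
growth_rate: 0.01
fixation_thresholds: [0.5]
success_threshold: 0.95
groups:
  - {n_groups: 3, niche_mode: homogeneous}
  - {n_groups: 3, niche_mode: heterogeneous}
  - {n_groups: 10, niche_mode: homogeneous}
  - {n_groups: 10, niche_mode: heterogeneous}
seed: 2
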