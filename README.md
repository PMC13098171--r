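# driftsim

Simulating whether neutral ecological drift, applied through serial
dilution–growth passaging, can distill a complex microbial community into a
**minimal microbiome** — a small consortium that keeps one population per
functional niche.

## Who this is for

Microbial ecologists and synthetic-community engineers planning (or
interpreting) serial-passage simplification experiments, who want a null
model: how fast does pure drift fix populations, which dilution factors and
community sizes make the protocol work, and when do minority functional
groups get lost at the bottleneck instead of simplified.

## The model

A community is an integer abundance vector over populations, optionally
partitioned into functional groups with fixed carrying capacities (niche
sizes). Each cycle:

1. **Dilution** — multinomial sampling with replacement down to
   `round(D · N)` individuals (`D` = dilution factor);
2. **Growth** — iterative stochastic regrowth: at iteration *k* the
   community gains `I_k = max(1, round(g · N_total(k−1)))` individuals
   (growth rate `g`, default 1%), allocated with probabilities

   `p_i(k) = N_i(k−1) / N_total(k−1)`

   or, within functional groups, `p_(i|G) = N_i / N_G` with each group
   receiving `I_k · f_G` individuals until it reaches its capacity
   `K_G = f_G · N_0`. Optional inter-group interactions perturb the
   probabilities as `p′ = p + A·p` with a sparse, unidirectional, signed
   matrix `A`.

A population **fixes** when its within-group relative abundance strictly
exceeds a fixation threshold (0.5 / 0.9), or when it is its group's sole
survivor; an experiment of replicate trajectories reaches **success** at
the first cycle where ≥ 95% of trajectories have a fixed population in
*every* group. The methods vignette
(`vignettes/dilution-growth-model.Rmd`) documents every choice the
equations leave open.

## Worked example

```r
library(driftsim)

comm <- generate_community(richness = 100, size = 10000,
                           distribution = "lognormal", seed = 1) |>
  assign_groups(n_groups = 3, niche_mode = "homogeneous", seed = 1)

diversity_metrics(comm)
#> # A tibble: 1 × 4
#>   richness shannon pielou  gini
#>      <int>   <dbl>  <dbl> <dbl>
#> 1      100    4.22  0.917 0.465

ex <- run_experiment(comm, dilution_factor = 0.01,
                     n_trajectories = 100, n_cycles = 200, seed = 42)
glance(success_profile(ex, fixation_threshold = 0.5,
                       success_threshold = 0.95))
#> # A tibble: 1 × 6
#>   earliest_success_cycle max_success_rate fixation_threshold success_threshold
#>                    <int>            <dbl>              <dbl>             <dbl>
#> 1                     26                1                0.5              0.95

group_rates(ex, at_cycle = 200)
#> # A tibble: 3 × 4
#>   group niche_fraction fixation_rate extinction_rate
#>   <int>          <dbl>         <dbl>           <dbl>
#> 1     1          0.333           100               0
#> 2     2          0.333           100               0
#> 3     3          0.333           100               0
```

Read: under a 1% transfer, all 100 replicate passage lines of this
log-normal community had one population fixed (>50%) in each of the three
niches by cycle 26, and no niche was ever lost — this setting would yield a
3-member minimal microbiome. `autoplot()` methods plot trajectories and
success profiles; `run_scenario()` executes whole parameter sweeps (shipped
configurations: `scenario_path("scenario1")` … `"scenario3"`, each with a
`_reduced` variant) with resumable, byte-reproducible output; the thin CLI
in `inst/exec/driftsim` exposes `generate` / `run` / `analyze` from a
shell.

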