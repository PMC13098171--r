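---
title: "The dilution-growth drift model behind driftsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dilution-growth drift model behind driftsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftsim)
```

## The question the simulator answers

Serial passaging — repeatedly diluting a microbial community into fresh
medium and letting it regrow — is a candidate protocol for distilling a
complex community into a *minimal microbiome*: a small consortium that
still covers every function (niche) of the original. If no population has
a fitness advantage, the only force changing composition is **ecological
drift**: random sampling at the dilution bottleneck and stochastic birth
during regrowth. driftsim simulates exactly this null process and asks
under which experimental settings (dilution factor, community size,
richness, abundance distribution, niche structure, interactions) drift
alone *fixes* one population per functional group, and how quickly.

## The model

A community is an integer abundance vector $N_1, \dots, N_S$ over $S$
populations, optionally partitioned into functional groups. One
**dilution–growth cycle** is:

1. **Dilution.** The community of size $N$ is sampled *with replacement*
   down to $\mathrm{round}(D \cdot N)$ individuals, a multinomial draw with
   probabilities $N_i / N$. $D \in (0,1)$ is the dilution factor.
   Populations drawn zero times are extinct. A target of zero individuals
   is a **collapse**: the community cannot be sustained at this dilution.
2. **Growth.** The community regrows to its carrying capacity in
   iterations. At iteration $k$ the increment is
   $I_k = \max(1, \mathrm{round}(g \cdot N_{\mathrm{total}}(k-1)))$
   with growth rate $g$ (default $0.01$, i.e. 1% of the current total per
   iteration). Without groups, the $I_k$ new individuals are allocated by
   one multinomial draw with probabilities equal to current relative
   abundances $p_i(k) = N_i(k-1)/N_{\mathrm{total}}(k-1)$ — growth is
   neutral. With groups, each unfinished group $G$ receives
   $\max(1, \mathrm{round}(I_k f_G))$ individuals ($f_G$ its niche
   fraction), allocated within the group by the conditional probabilities
   $N_i(k-1)/N_G(k-1)$, and stops exactly at its capacity
   $K_G = f_G \cdot N_0$. Capacities are fixed from the *initial* total
   $N_0$ and never redistributed: when a group dies at a bottleneck its
   capacity is removed and total community size shrinks, which is the
   behaviour one expects of an emptied niche on the timescale of a passage
   experiment.

Inter-group **interactions** enter through a sparse signed matrix $A$,
where $A_{ij}$ is the effect of population $j$ on the growth probability
of population $i$:
$p'_i(k) = p_i(k) + \sum_j A_{ij}\, p_j(k).$
Interactions are inter-group only and unidirectional ($A_{ij} \neq 0
\Rightarrow A_{ji} = 0$), with a single absolute strength and a
configurable frequency (fraction of distinct inter-group population pairs
that interact).

**Fixation** is declared per scope (group, or the whole community) when a
population's within-scope relative abundance strictly exceeds the fixation
threshold (0.5 or 0.9 in the shipped designs), or when it is the scope's
sole survivor — the sole-survivor clause makes a threshold of 1.0 mean
"exactly one population left". An **experiment** is a set of replicate
trajectories of one initial community; its **success rate** at a cycle is
the fraction of trajectories in which *every* functional group has a fixed
population, and the experiment reaches **success** at the first cycle
where that rate meets the success threshold (default 95%).

## Choices the equations do not pin down

Several details are deliberate design decisions of this package, chosen
once and documented here rather than exposed as an unprincipled surface:

* **Rounding.** All size targets use round-half-to-even (base R's
  `round()`), in R and in the compiled engine alike. A dilution target of
  zero collapses the trajectory.
* **Increments.** $I_k$ is recomputed from the current total each
  iteration and floored at 1 individual (likewise each group's share), so
  growth always progresses even in tiny or strongly-diluted communities.
* **Allocation.** Each scope's $I_k$ individuals are assigned in a single
  multinomial draw per iteration. Adding individuals one at a time is the
  same process in expectation; the blocked draw is what makes large
  communities tractable.
* **Interaction scope.** The interaction term uses *global* relative
  abundances $p_j$ while grouped growth uses conditional within-group base
  probabilities: the perturbation expresses a dependency on how much of a
  partner population is present in the whole community. Perturbed
  probabilities are clipped at zero and renormalised within the scope; a
  scope whose probabilities sum to zero simply does not grow that
  iteration.
* **Overshoot.** When a blocked allocation or a with-replacement dilution
  leaves a group above its capacity, the excess is removed uniformly at
  random from the individuals just added (or from the group), so every
  completed growth phase ends with surviving groups exactly at capacity.
* **Group membership** is round-robin after a seeded shuffle (near-equal
  group sizes); heterogeneous niche fractions are drawn log-uniformly on
  $[0.001, 1]$ and renormalised, re-drawing until no group sits below
  0.1% — matching the regime where minority niches are genuinely at risk
  of extinction. Both can be overridden with explicit memberships or
  fractions.
* **Log-normal draws** use `meanlog = 0`, `sdlog = 1` (configurable), are
  scaled to the target size, and rounded by largest remainder with a
  minimum of one individual per population, so totals are exact.
* **Interaction pairs.** "Frequency" counts distinct (unordered)
  inter-group population pairs; a selected pair receives a random
  direction. At 100% frequency every inter-group pair interacts exactly
  once, which is the only reading consistent with unidirectionality.

## Reproducibility and seeds

Every generator takes an explicit seed; nothing depends on hidden RNG
state. Replicate structures (communities, group assignments, experiments,
trajectories) get child seeds through `child_seeds()`: a 64-bit mix of the
master seed followed by an affine bijection on the child index, reduced
mod $2^{31}$. Distinct indices can never collide, so a million
trajectories carry a million distinct seeds, and any single experiment can
be re-run bit-identically in isolation — which is also why `run_scenario()`
results do not depend on the number of worker processes, and why an
interrupted scenario can be resumed without changing a byte of its output.

A performance note: once a single population remains in the whole
community (and dilution can no longer collapse it) every later cycle ends
in exactly the same state, so `run_trajectory(early_stop = TRUE)` fills
the remaining cycles without simulating them. This is an exact shortcut,
not an approximation, and is verified against the full run in the tests.

## What the tests establish — and on what scales

The test suite checks the simulator against independent oracles rather
than against itself:

* an **exact absorbing Markov chain** for a 2-population, size-10,
  one-scope community with unit growth increments (dilution kernel
  $\times$ one-at-a-time growth, built by dynamic programming and
  cross-checked against the Pólya-urn closed form); simulated per-cycle
  fixation probabilities from $10^5$ trajectories match it cycle by cycle;
* the **neutral-drift fixation law**: a population's probability of
  eventually fixing equals its initial relative abundance (checked at
  10% over $10^4$ size-100 trajectories, binomial 99% interval);
* the **martingale property** of relative abundance over a full cycle
  ($10^4$ single cycles from 50/50 at size $10^4$, $D = 0.01$);
* exact **capacity conservation** at every one of 1000 fuzzed cycles; and
* the qualitative ordering effects of the design parameters: success
  arrives earlier under stronger dilution and in smaller communities (median
  earliest success cycle over log-normal richness-100 communities of size
  $10^3$ and $10^4$ at $D \in \{0.1, 0.01, 0.001\}$, 50 trajectories, 3
  replicate communities).

The shipped full-scale scenario configurations expand to their printed
design counts (12 combinations / 360 communities / 5040 experiments /
504,000 trajectories for the opening design), but the stochastic checks
above run at the reduced scales listed, chosen to exercise every code
path in minutes on a laptop; reduced `*_reduced` configurations are
provided for the same purpose.

## What the generator does and does not emulate

Initial communities are exchangeable labels with uniform or log-normal
abundances; there is no phylogeny, no taxonomy, no spatial structure, no
immigration, no mutation, and no intra-group interaction — the simulator
is a *null model* for drift under passaging, not a fitted model of any
particular ecosystem. Passing tests therefore demonstrate the internal
consistency of the drift process and its analysis, not that a real
community will behave neutrally; in real experiments selection,
cross-feeding and environmental fluctuation are superimposed on the drift
floor this package quantifies.

## Known limitations

* Success-rate curves are computed from each cycle's recorded end state;
  with multiple groups, fixation is not strictly absorbing (a dominant
  population can slip back below the threshold), so success can
  transiently dip — `success_profile()` reports the first threshold
  crossing.
* The definition of group extinction is demographic (zero individuals).
  Analyses that call a group "extinct" whenever nothing fixed in it
  conflate those two outcomes; driftsim reports them separately
  (`group_rates()` returns both).
* Very strong negative interactions can drive all of a scope's
  probabilities to zero; the scope then pauses rather than shrinking,
  which is one of several defensible readings of the model at that
  extreme.
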