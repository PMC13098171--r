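# small builders shared across test files

two_pop_community <- function(a, b, group = NULL) {
  comm <- tibble::tibble(
    population = c("popA", "popB"),
    abundance = as.integer(c(a, b))
  )
  if (!is.null(group)) comm$group <- as.integer(group)
  comm
}

# hand-built drift_experiment from an explicit states array
# states: cycles x populations x trajectories integer array
fake_experiment <- function(states, group = NULL, niche_fractions = NULL) {
  np <- dim(states)[2]
  group <- group %||% rep(1L, np)
  nf <- niche_fractions %||%
    as.numeric(table(factor(group, levels = sort(unique(group)))) / np)
  structure(
    list(
      states = states,
      final = matrix(states[dim(states)[1], , ], nrow = np),
      status = rep("completed", dim(states)[3]),
      collapse_cycle = rep(NA_integer_, dim(states)[3]),
      absorbed_cycle = rep(NA_integer_, dim(states)[3]),
      community = tibble::tibble(
        population = paste0("pop", seq_len(np)),
        abundance = states[1, , 1],
        group = group
      ),
      group = group,
      niche_fractions = nf,
      capacity = NULL,
      dilution_factor = 0.1,
      growth_rate = 0.01,
      n_cycles = dim(states)[1],
      n_trajectories = dim(states)[3],
      seed = 0L,
      seeds = seq_len(dim(states)[3])
    ),
    class = "drift_experiment"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
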