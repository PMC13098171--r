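#' Dilute a community by multinomial sampling
#'
#' Simulates one transfer: the community is sampled with replacement down to
#' `round(D * N)` individuals (round half to even), so each surviving count
#' is a multinomial draw with probabilities equal to current relative
#' abundances. Populations drawn zero times are extinct in the diluted
#' community. A target size of zero returns an all-zero community, the
#' collapse signal used by [run_trajectory()].
#'
#' @param community A community tibble.
#' @param dilution_factor Fraction `D` in (0, 1) of the community that
#'   survives the transfer.
#' @param seed Optional integer seed; otherwise the current RNG state is
#'   used.
#' @return The diluted community tibble (attributes preserved).
#' @examples
#' comm <- generate_community(10, 1e4, seed = 1)
#' sum(dilute(comm, 0.01, seed = 1)$abundance)
#' @export
dilute <- function(community, dilution_factor, seed = NULL) {
  community <- as_community(community)
  stopifnot(dilution_factor > 0, dilution_factor < 1)
  if (!is.null(seed)) set.seed(seed)
  N <- sum(community$abundance)
  if (N < 1) abort("cannot dilute an empty community")
  target <- round(dilution_factor * N)
  out <- community
  if (target < 1) {
    out$abundance <- 0L
  } else {
    out$abundance <- as.integer(rmultinom(1, target, community$abundance))
  }
  out
}

#' Per-population growth probabilities
#'
#' Computes the probability that the next grown individual belongs to each
#' population. Without groups this is the global relative abundance
#' `N_i / N_total`; with groups it is the within-group relative abundance
#' `N_i / N_G` (extinct groups get zero). An interaction matrix `A` adds
#' `sum_j A[i, j] * p_j` with `p_j` the global relative abundance; negative
#' results are clipped to zero and each scope is renormalised to sum to 1.
#'
#' @param community A community tibble (with or without groups).
#' @param interactions Optional square interaction matrix.
#' @return A tibble with columns `population`, `group`, and `probability`.
#'   Probabilities sum to 1 within each non-extinct scope.
#' @examples
#' comm <- generate_community(5, 100, seed = 1)
#' growth_probabilities(comm)
#' @export
growth_probabilities <- function(community, interactions = NULL) {
  community <- as_community(community)
  N <- sum(community$abundance)
  if (N < 1) abort("cannot compute growth probabilities for an empty community")
  grp <- community[["group"]] %||% rep(1L, nrow(community))

  p_global <- community$abundance / N
  ng <- tapply(community$abundance, grp, sum)[as.character(grp)]
  p <- ifelse(ng > 0, community$abundance / ng, 0)
  if (!is.null(interactions)) {
    if (!is.matrix(interactions) || any(dim(interactions) != nrow(community))) {
      abort("interaction matrix must be square over the community's populations")
    }
    p <- p + as.vector(interactions %*% p_global)
    p[p < 0] <- 0
    p[ng == 0] <- 0
  }
  # renormalise within each scope
  scope_sum <- tapply(p, grp, sum)[as.character(grp)]
  p <- ifelse(scope_sum > 0, p / scope_sum, 0)

  tibble::tibble(
    population = community$population,
    group = as.integer(grp),
    probability = as.numeric(p)
  )
}

#' Regrow a community to its carrying capacity
#'
#' Runs the iterative stochastic growth phase: at each iteration the global
#' increment is `I_k = max(1, round(growth_rate * N_total))` new individuals;
#' without groups they are allocated by one multinomial draw over current
#' relative abundances, with groups each unfinished group receives
#' `max(1, round(I_k * niche_fraction))` individuals allocated within the
#' group, and growth stops when every surviving group sits exactly at its
#' carrying capacity (overshoot is trimmed uniformly from the final
#' allocation).
#'
#' @inheritParams dilute
#' @param target_total Total size to grow back to; defaults to the current
#'   total (useful after [dilute()] only when set explicitly). Group
#'   capacities are apportioned from niche fractions by largest remainder.
#' @param interactions Optional square interaction matrix.
#' @param growth_rate Fraction of the current total added per iteration
#'   (default 0.01, i.e. 1% growth steps).
#' @return The regrown community tibble.
#' @examples
#' comm <- generate_community(10, 1000, seed = 1)
#' small <- dilute(comm, 0.1, seed = 2)
#' sum(growth_phase(small, target_total = 1000, seed = 3)$abundance)
#' @export
growth_phase <- function(community, target_total = NULL, interactions = NULL,
                         growth_rate = 0.01, seed = NULL) {
  community <- as_community(community)
  if (!is.null(seed)) set.seed(seed)
  N <- sum(community$abundance)
  if (N < 1) abort("cannot grow an empty community")
  if (is.null(target_total)) target_total <- N
  if (target_total < N) abort("`target_total` must be >= the current total")

  eng <- engine_inputs(community, target_total, drop_extinct = TRUE)
  tri <- interaction_triplets(interactions, community)
  out <- community
  out$abundance <- cpp_growth_phase(
    eng$abundance, eng$group0, eng$capacity, eng$frac,
    tri$i, tri$j, tri$x, growth_rate
  )
  out
}

#' Run one dilution-growth trajectory
#'
#' Alternates [dilute()] and [growth_phase()] for `n_cycles` cycles. Group
#' carrying capacities are fixed before the first cycle as
#' `niche_fraction * initial total` (largest-remainder apportionment); a
#' group diluted to zero is permanently extinct and its capacity is removed
#' from the growth target, so total community size shrinks. A dilution that
#' empties the community terminates the trajectory with status
#' `"collapsed"`.
#'
#' @inheritParams growth_phase
#' @param dilution_factor Fraction `D` in (0, 1) surviving each transfer.
#' @param n_cycles Number of dilution-growth cycles.
#' @param interactions `NULL`, a fixed square interaction matrix, or an
#'   [interaction_spec()] (a fresh matrix is drawn for the trajectory).
#' @param seed Integer seed for the trajectory.
#' @param record `"all"` to store the end state of every cycle, `"final"`
#'   to store only the last state.
#' @param early_stop When `TRUE` (default) the cycle loop stops once a
#'   single population remains and cannot collapse: from then on every
#'   cycle ends in exactly the same state, which is filled in for the
#'   remaining cycles. Results are identical to running all cycles.
#' @return A `drift_trajectory` object; see [tidy.drift_trajectory()] and
#'   [glance.drift_trajectory()].
#' @examples
#' comm <- generate_community(10, 1000, seed = 1)
#' tr <- run_trajectory(comm, dilution_factor = 0.01, n_cycles = 50, seed = 1)
#' glance(tr)
#' @export
run_trajectory <- function(community, dilution_factor, n_cycles = 200,
                           growth_rate = 0.01, interactions = NULL,
                           seed = NULL, record = c("all", "final"),
                           early_stop = TRUE) {
  community <- as_community(community)
  record <- match.arg(record)
  stopifnot(dilution_factor > 0, dilution_factor < 1, n_cycles >= 1,
            growth_rate > 0, growth_rate <= 1)
  if (!is.null(seed)) set.seed(seed)

  A <- interactions
  if (inherits(interactions, "interaction_spec")) {
    A <- generate_interaction_matrix(community, interactions)
  }
  tri <- interaction_triplets(A, community)
  eng <- engine_inputs(community, sum(community$abundance))

  res <- cpp_run_trajectory(
    eng$abundance, eng$group0, eng$capacity, eng$frac,
    tri$i, tri$j, tri$x,
    dilution_factor, growth_rate, as.integer(n_cycles),
    record == "all", early_stop
  )

  structure(
    list(
      states = if (record == "all") {
        `colnames<-`(res$states, community$population)
      } else NULL,
      final = setNames(res$final, community$population),
      status = res$status,
      collapse_cycle = if (res$collapse_cycle > 0) res$collapse_cycle else NA_integer_,
      absorbed_cycle = if (res$absorbed_cycle > 0) res$absorbed_cycle else NA_integer_,
      n_recorded = res$n_recorded,
      community = community,
      group = eng$group0 + 1L,
      niche_fractions = eng$frac,
      capacity = setNames(eng$capacity, seq_along(eng$capacity)),
      dilution_factor = dilution_factor,
      growth_rate = growth_rate,
      n_cycles = n_cycles,
      seed = seed
    ),
    class = "drift_trajectory"
  )
}

# shared conversion community -> engine vectors; capacities apportioned by
# largest remainder from the niche fractions so they sum to target_total
engine_inputs <- function(community, target_total, drop_extinct = FALSE) {
  grp <- community[["group"]]
  if (is.null(grp)) {
    return(list(
      abundance = as.integer(community$abundance),
      group0 = rep(0L, nrow(community)),
      capacity = as.integer(target_total),
      frac = 1
    ))
  }
  nf <- niche_fractions(community)
  cap <- largest_remainder(nf, target_total)
  if (drop_extinct) {
    ng <- tapply(community$abundance, factor(grp, levels = seq_along(nf)), sum)
    ng[is.na(ng)] <- 0
    cap[ng == 0] <- 0L
  }
  list(
    abundance = as.integer(community$abundance),
    group0 = as.integer(grp) - 1L,
    capacity = cap,
    frac = as.numeric(nf)
  )
}

#' Run replicate trajectories of one experiment
#'
#' Runs `n_trajectories` independent trajectories of the same initial
#' community under identical settings, each with its own child seed derived
#' from `seed` by the package's collision-free splitting rule
#' ([child_seeds()]), so results are reproducible at any level of
#' parallelism. When `interactions` is an [interaction_spec()], each
#' trajectory draws a fresh random interaction matrix, seeded by its child
#' seed.
#'
#' @inheritParams run_trajectory
#' @param n_trajectories Number of replicate trajectories.
#' @param cores Number of worker processes (forked; `1` = sequential).
#' @return A `drift_experiment` object holding per-cycle states of every
#'   trajectory (when `record = "all"`), per-trajectory status, and the
#'   experiment settings.
#' @examples
#' comm <- generate_community(10, 500, seed = 1)
#' ex <- run_experiment(comm, 0.05, n_trajectories = 10, n_cycles = 30, seed = 1)
#' glance(ex)
#' @export
run_experiment <- function(community, dilution_factor, n_trajectories = 100,
                           n_cycles = 200, growth_rate = 0.01,
                           interactions = NULL, seed = NULL,
                           record = c("all", "final"), cores = 1,
                           early_stop = TRUE) {
  community <- as_community(community)
  record <- match.arg(record)
  stopifnot(dilution_factor > 0, dilution_factor < 1, n_cycles >= 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  seeds <- child_seeds(seed, seq_len(n_trajectories))

  # hoist the shared conversions out of the trajectory loop; each
  # trajectory then only seeds the RNG (and, for an interaction_spec,
  # draws its fresh matrix) before entering the compiled engine
  eng <- engine_inputs(community, sum(community$abundance))
  fresh_matrix <- inherits(interactions, "interaction_spec")
  tri <- if (fresh_matrix) NULL else interaction_triplets(interactions, community)

  run_one <- function(s) {
    set.seed(s)
    tr <- if (fresh_matrix) {
      interaction_triplets(
        generate_interaction_matrix(community, interactions), community
      )
    } else tri
    cpp_run_trajectory(
      eng$abundance, eng$group0, eng$capacity, eng$frac,
      tr$i, tr$j, tr$x,
      dilution_factor, growth_rate, as.integer(n_cycles),
      record == "all", early_stop
    )
  }
  trajectories <- if (cores > 1) {
    parallel::mclapply(seeds, run_one, mc.cores = cores)
  } else {
    lapply(seeds, run_one)
  }

  states <- NULL
  if (record == "all") {
    states <- array(
      0L,
      dim = c(n_cycles, nrow(community), n_trajectories),
      dimnames = list(NULL, community$population, NULL)
    )
    for (t in seq_len(n_trajectories)) states[, , t] <- trajectories[[t]]$states
  }
  final <- vapply(trajectories, function(tr) tr$final, integer(nrow(community)))

  structure(
    list(
      states = states,
      final = matrix(final, nrow = nrow(community),
                     dimnames = list(community$population, NULL)),
      status = vapply(trajectories, function(tr) tr$status, character(1)),
      collapse_cycle = vapply(trajectories, function(tr) {
        if (tr$collapse_cycle > 0) tr$collapse_cycle else NA_integer_
      }, integer(1)),
      absorbed_cycle = vapply(trajectories, function(tr) {
        if (tr$absorbed_cycle > 0) tr$absorbed_cycle else NA_integer_
      }, integer(1)),
      community = community,
      group = eng$group0 + 1L,
      niche_fractions = eng$frac,
      capacity = setNames(eng$capacity, seq_along(eng$capacity)),
      dilution_factor = dilution_factor,
      growth_rate = growth_rate,
      n_cycles = n_cycles,
      n_trajectories = n_trajectories,
      seed = seed,
      seeds = seeds
    ),
    class = "drift_experiment"
  )
}

#' @export
print.drift_trajectory <- function(x, ...) {
  cat(sprintf(
    "<drift_trajectory> %d populations, D = %g, %d cycles, status: %s\n",
    length(x$final), x$dilution_factor, x$n_cycles, x$status
  ))
  invisible(x)
}

#' @export
print.drift_experiment <- function(x, ...) {
  cat(sprintf(
    "<drift_experiment> %d trajectories x %d cycles, %d populations, D = %g\n",
    x$n_trajectories, x$n_cycles, length(x$community$population),
    x$dilution_factor
  ))
  cat(sprintf("  collapsed: %d/%d\n", sum(x$status == "collapsed"),
              x$n_trajectories))
  invisible(x)
}

#' Tidy a trajectory into a long cycle-by-population table
#'
#' @param x A `drift_trajectory`.
#' @param ... Unused.
#' @return A tibble with columns `cycle`, `population`, `group`, `abundance`.
#' @export
tidy.drift_trajectory <- function(x, ...) {
  if (is.null(x$states)) {
    return(tibble::tibble(
      cycle = x$n_recorded,
      population = names(x$final),
      group = x$group,
      abundance = as.integer(x$final)
    ))
  }
  out <- tibble::as_tibble(as.data.frame(x$states))
  out$cycle <- seq_len(nrow(out))
  out <- tidyr::pivot_longer(out, -"cycle",
    names_to = "population", values_to = "abundance"
  )
  out$group <- x$group[match(out$population, names(x$final))]
  dplyr::arrange(out[, c("cycle", "population", "group", "abundance")],
                 .data$cycle, .data$population)
}

#' One-row summary of a trajectory
#'
#' @param x A `drift_trajectory`.
#' @param ... Unused.
#' @return A one-row tibble: status, collapse/absorption cycles, final
#'   richness and total size.
#' @export
glance.drift_trajectory <- function(x, ...) {
  tibble::tibble(
    status = x$status,
    n_cycles = x$n_cycles,
    collapse_cycle = x$collapse_cycle,
    absorbed_cycle = x$absorbed_cycle,
    final_richness = sum(x$final > 0),
    final_size = sum(x$final)
  )
}

#' Per-trajectory summaries of an experiment
#'
#' @param x A `drift_experiment`.
#' @param ... Unused.
#' @return A tibble with one row per trajectory.
#' @export
tidy.drift_experiment <- function(x, ...) {
  tibble::tibble(
    trajectory = seq_len(x$n_trajectories),
    seed = x$seeds,
    status = x$status,
    collapse_cycle = x$collapse_cycle,
    absorbed_cycle = x$absorbed_cycle,
    final_richness = colSums(x$final > 0)
  )
}

#' One-row summary of an experiment
#'
#' @param x A `drift_experiment`.
#' @param ... Unused.
#' @return A one-row tibble with settings and aggregate outcomes.
#' @export
glance.drift_experiment <- function(x, ...) {
  tibble::tibble(
    n_trajectories = x$n_trajectories,
    n_cycles = x$n_cycles,
    dilution_factor = x$dilution_factor,
    growth_rate = x$growth_rate,
    prop_collapsed = mean(x$status == "collapsed"),
    mean_final_richness = mean(colSums(x$final > 0))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
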