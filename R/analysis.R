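#' Fixation detection in a single community state
#'
#' A population is fixed within its scope (its functional group, or the
#' whole community when no groups are assigned) when its relative abundance
#' within that scope STRICTLY exceeds the fixation threshold. At thresholds
#' of 0.5 and above at most one population per scope can qualify. A scope
#' with zero individuals is extinct and has no fixed population; the sole
#' surviving population of a scope is fixed at any threshold.
#'
#' @param community A community tibble (a state, e.g. one cycle's end state).
#' @param fixation_threshold Relative abundance in (0, 1] a population must
#'   exceed (default 0.5).
#' @return A tibble with one row per group: `group`, `population` (fixed
#'   population ID or `NA`), `relative_abundance`, `extinct`.
#' @examples
#' comm <- tibble::tibble(
#'   population = c("a", "b"), abundance = c(60L, 40L)
#' )
#' detect_fixation(comm)
#' @export
detect_fixation <- function(community, fixation_threshold = 0.5) {
  community <- as_community(community)
  stopifnot(fixation_threshold > 0, fixation_threshold <= 1)
  grp <- community[["group"]] %||% rep(1L, nrow(community))

  purrr::map_dfr(sort(unique(grp)), function(g) {
    idx <- which(grp == g)
    tot <- sum(community$abundance[idx])
    if (tot == 0) {
      return(tibble::tibble(
        group = g, population = NA_character_,
        relative_abundance = NA_real_, extinct = TRUE
      ))
    }
    top <- idx[which.max(community$abundance[idx])]
    rel <- community$abundance[top] / tot
    sole <- sum(community$abundance[idx] > 0) == 1
    tibble::tibble(
      group = g,
      population = if (rel > fixation_threshold || sole) {
        community$population[top]
      } else NA_character_,
      relative_abundance = rel,
      extinct = FALSE
    )
  })
}

# internal: per-cycle, per-group, per-trajectory logical arrays of fixation
# and extinction, computed from an experiment's recorded states
fixation_arrays <- function(experiment, fixation_threshold) {
  st <- experiment$states
  if (is.null(st)) {
    abort("experiment was run with `record = \"final\"`; per-cycle analysis needs `record = \"all\"`")
  }
  grp <- experiment$group
  groups <- sort(unique(grp))
  nc <- dim(st)[1]; nt <- dim(st)[3]
  fixed <- array(FALSE, dim = c(nc, length(groups), nt))
  extinct <- array(FALSE, dim = c(nc, length(groups), nt))
  for (gi in seq_along(groups)) {
    cols <- which(grp == groups[gi])
    sub <- st[, cols, , drop = FALSE]
    tot <- colSums(aperm(sub, c(2, 1, 3)))        # cycles x trajectories
    alive <- colSums(aperm(sub, c(2, 1, 3)) > 0)  # surviving populations
    mx <- sub[, 1, ]
    if (length(cols) > 1) {
      for (j in 2:length(cols)) mx <- pmax(mx, sub[, j, ])
    }
    mx <- matrix(mx, nrow = nc)
    # a sole surviving population is fixed at any threshold
    fixed[, gi, ] <- tot > 0 & (mx > fixation_threshold * tot | alive == 1)
    extinct[, gi, ] <- tot == 0
  }
  list(fixed = fixed, extinct = extinct, groups = groups)
}

#' Success profile of a replicated experiment
#'
#' A trajectory is successful at a cycle when every relevant functional
#' group contains a fixed population at that cycle's recorded state; the
#' success rate is the fraction of trajectories that are successful, and the
#' experiment reaches success at the first cycle where the success rate
#' meets the success threshold. Success does not require the same population
#' to fix across trajectories.
#'
#' @param experiment A `drift_experiment` run with `record = "all"`.
#' @param fixation_threshold Within-group relative abundance a population
#'   must strictly exceed to count as fixed (default 0.5).
#' @param success_threshold Minimum success rate for the experiment to be
#'   declared successful (default 0.95).
#' @param extinct_groups `"fail"` (default): a trajectory with any extinct
#'   group can never be successful — full success requires fixation in every
#'   group. `"ignore"`: the requirement is restricted to groups still alive
#'   in that trajectory at that cycle (partial-success analysis); a
#'   trajectory with no surviving group is still a failure.
#' @return A `drift_success` object; `tidy()` gives the per-cycle success
#'   rates, `glance()` the earliest success cycle.
#' @examples
#' comm <- generate_community(5, 200, seed = 1)
#' ex <- run_experiment(comm, 0.05, n_trajectories = 20, n_cycles = 50, seed = 2)
#' glance(success_profile(ex))
#' @export
success_profile <- function(experiment, fixation_threshold = 0.5,
                            success_threshold = 0.95,
                            extinct_groups = c("fail", "ignore")) {
  stopifnot(inherits(experiment, "drift_experiment"))
  stopifnot(success_threshold > 0, success_threshold <= 1)
  extinct_groups <- match.arg(extinct_groups)
  fa <- fixation_arrays(experiment, fixation_threshold)

  ok_gct <- if (extinct_groups == "fail") fa$fixed else fa$fixed | fa$extinct
  # success per cycle x trajectory: all groups ok, and at least one alive
  success_ct <- apply(ok_gct, c(1, 3), all) &
    !apply(fa$extinct, c(1, 3), all)
  rate <- rowMeans(success_ct)

  by_cycle <- tibble::tibble(
    cycle = seq_along(rate),
    n_successful = as.integer(rowSums(success_ct)),
    success_rate = rate
  )
  hit <- which(rate >= success_threshold)
  structure(
    list(
      by_cycle = by_cycle,
      earliest_success_cycle = if (length(hit)) hit[1] else NA_integer_,
      fixation_threshold = fixation_threshold,
      success_threshold = success_threshold,
      extinct_groups = extinct_groups,
      n_trajectories = experiment$n_trajectories,
      dilution_factor = experiment$dilution_factor
    ),
    class = "drift_success"
  )
}

#' @export
print.drift_success <- function(x, ...) {
  cat(sprintf(
    "<drift_success> fixation > %g, success >= %g over %d trajectories\n",
    x$fixation_threshold, x$success_threshold, x$n_trajectories
  ))
  if (is.na(x$earliest_success_cycle)) {
    cat("  never successful within the recorded cycles\n")
  } else {
    cat(sprintf("  earliest success cycle: %d\n", x$earliest_success_cycle))
  }
  invisible(x)
}

#' @rdname success_profile
#' @param x A `drift_success` object.
#' @param ... Unused.
#' @export
tidy.drift_success <- function(x, ...) x$by_cycle

#' @rdname success_profile
#' @export
glance.drift_success <- function(x, ...) {
  tibble::tibble(
    earliest_success_cycle = x$earliest_success_cycle,
    max_success_rate = max(x$by_cycle$success_rate),
    fixation_threshold = x$fixation_threshold,
    success_threshold = x$success_threshold,
    n_trajectories = x$n_trajectories,
    dilution_factor = x$dilution_factor
  )
}

#' Per-group fixation and extinction rates
#'
#' Fixation rate of a group is the percentage of trajectories in which at
#' least one of its populations is fixed at the evaluated cycle; extinction
#' rate is the percentage of trajectories in which the group holds zero
#' individuals. A group can be neither fixed nor extinct, so the two rates
#' need not sum to 100%.
#'
#' @inheritParams success_profile
#' @param at_cycle Cycle at which rates are evaluated (default: last cycle).
#' @return A tibble with one row per group: `group`, `niche_fraction`,
#'   `fixation_rate`, `extinction_rate` (percent of trajectories).
#' @examples
#' comm <- generate_community(6, 300, seed = 1) |>
#'   assign_groups(3, seed = 1)
#' ex <- run_experiment(comm, 0.05, n_trajectories = 20, n_cycles = 50, seed = 2)
#' group_rates(ex)
#' @export
group_rates <- function(experiment, fixation_threshold = 0.5,
                        at_cycle = NULL) {
  stopifnot(inherits(experiment, "drift_experiment"))
  fa <- fixation_arrays(experiment, fixation_threshold)
  nc <- dim(fa$fixed)[1]
  at_cycle <- at_cycle %||% nc
  if (at_cycle < 1 || at_cycle > nc) abort("`at_cycle` outside the recorded range")
  tibble::tibble(
    group = fa$groups,
    niche_fraction = experiment$niche_fractions[fa$groups],
    fixation_rate = 100 * rowMeans(matrix(fa$fixed[at_cycle, , ],
                                          nrow = length(fa$groups))),
    extinction_rate = 100 * rowMeans(matrix(fa$extinct[at_cycle, , ],
                                            nrow = length(fa$groups)))
  )
}

#' Community diversity metrics
#'
#' Richness (populations with non-zero abundance), Shannon diversity
#' `H = -sum p_i log p_i` (natural log, via [vegan::diversity()]), Pielou's
#' evenness `H / log(richness)` (1 for a single population, by the limit
#' convention), and the Gini index of the abundance vector.
#'
#' @param community A community tibble with at least one individual.
#' @return A one-row tibble: `richness`, `shannon`, `pielou`, `gini`.
#' @examples
#' diversity_metrics(generate_community(10, 1000, seed = 1))
#' @export
diversity_metrics <- function(community) {
  community <- as_community(community)
  ab <- community$abundance
  if (sum(ab) < 1) abort("cannot compute diversity of an empty community")
  rich <- sum(ab > 0)
  h <- as.numeric(vegan::diversity(ab, index = "shannon"))
  tibble::tibble(
    richness = rich,
    shannon = h,
    pielou = if (rich > 1) h / log(rich) else 1,
    gini = gini_index(ab)
  )
}

# Gini coefficient of a non-negative count vector (0 = perfectly even)
gini_index <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n == 1 || sum(x) == 0) return(0)
  (2 * sum(seq_len(n) * x)) / (n * sum(x)) - (n + 1) / n
}
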