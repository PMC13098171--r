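#' Generate a synthetic initial community
#'
#' Draws population abundances from a uniform or log-normal distribution and
#' converts them to non-negative integer counts that sum exactly to `size`,
#' with every population receiving at least one individual. This is the
#' simulated analogue of an initial complex community before any passaging.
#'
#' Continuous draws are scaled to the target total and rounded with a
#' largest-remainder repair so the integer total is exact; populations rounded
#' to zero are topped up to one individual, taking the difference from the
#' most abundant populations.
#'
#' @param richness Number of distinct populations (>= 1).
#' @param size Total number of individuals; must be >= `richness` so every
#'   population can hold at least one individual.
#' @param distribution Abundance distribution, `"uniform"` or `"lognormal"`.
#' @param seed Optional integer seed; when supplied the draw is reproducible.
#' @param meanlog,sdlog Log-normal parameters (used when
#'   `distribution = "lognormal"`).
#'
#' @return A community: a tibble with columns `population` (character label)
#'   and `abundance` (integer count).
#'
#' @examples
#' comm <- generate_community(10, 1e4, "uniform", seed = 1)
#' sum(comm$abundance)
#' @export
generate_community <- function(richness, size,
                               distribution = c("uniform", "lognormal"),
                               seed = NULL, meanlog = 0, sdlog = 1) {
  distribution <- match.arg(distribution)
  if (richness < 1) abort("`richness` must be >= 1")
  if (size < richness) {
    abort("`size` must be >= `richness`: every population needs at least one individual")
  }
  if (!is.null(seed)) set.seed(seed)

  w <- switch(distribution,
    uniform = runif(richness),
    lognormal = rlnorm(richness, meanlog = meanlog, sdlog = sdlog)
  )
  ab <- largest_remainder(w, size)
  ab <- repair_minimum(ab)

  tibble::tibble(population = pop_labels(richness), abundance = ab)
}

#' Assign populations to functional groups
#'
#' Partitions the community's populations into `n_groups` functional groups
#' and attaches per-group niche fractions (the share of total community size
#' each group's carrying capacity occupies). Membership is assigned
#' round-robin after a seeded shuffle unless supplied explicitly, so group
#' sizes are near-equal. Homogeneous niches give every group the fraction
#' `1/n_groups`; heterogeneous niches are drawn log-uniformly on
#' [0.001, 1] and renormalised, re-drawing until no group falls below a
#' relative abundance of 0.1%.
#'
#' @param community A community tibble (see [generate_community()]).
#' @param n_groups Number of functional groups; must not exceed the number of
#'   populations.
#' @param niche_mode `"homogeneous"` or `"heterogeneous"`; ignored when
#'   `niche_fractions` is supplied.
#' @param niche_fractions Optional explicit per-group fractions summing to 1.
#' @param membership Optional integer vector (values in `1:n_groups`, one per
#'   population) giving explicit group membership.
#' @param seed Optional integer seed.
#'
#' @return The community tibble with an added integer `group` column and a
#'   `niche_fractions` attribute; retrieve the group table with
#'   [group_spec()].
#'
#' @examples
#' comm <- generate_community(100, 1e4, seed = 1)
#' comm <- assign_groups(comm, 3, "homogeneous", seed = 1)
#' group_spec(comm)
#' @export
assign_groups <- function(community, n_groups,
                          niche_mode = c("homogeneous", "heterogeneous"),
                          niche_fractions = NULL, membership = NULL,
                          seed = NULL) {
  community <- as_community(community)
  niche_mode <- match.arg(niche_mode)
  n <- nrow(community)
  if (n_groups > n) abort("`n_groups` cannot exceed the number of populations")
  if (!is.null(seed)) set.seed(seed)

  if (is.null(membership)) {
    membership <- integer(n)
    membership[sample.int(n)] <- rep_len(seq_len(n_groups), n)
  } else {
    membership <- as.integer(membership)
    if (length(membership) != n || !setequal(unique(membership), seq_len(n_groups))) {
      abort("`membership` must cover every group with one entry per population")
    }
  }

  if (is.null(niche_fractions)) {
    niche_fractions <- switch(niche_mode,
      homogeneous = rep(1 / n_groups, n_groups),
      heterogeneous = draw_heterogeneous_fractions(n_groups)
    )
  } else {
    if (length(niche_fractions) != n_groups) {
      abort("`niche_fractions` must have one entry per group")
    }
    if (any(niche_fractions <= 0) || abs(sum(niche_fractions) - 1) > 1e-9) {
      abort("`niche_fractions` must be strictly positive and sum to 1")
    }
  }

  community$group <- membership
  attr(community, "niche_fractions") <- as.numeric(niche_fractions)
  community
}

# log-uniform fractions on [0.001, 1], renormalised; re-draw while any group
# would sit below the 0.1% floor
draw_heterogeneous_fractions <- function(n_groups, floor = 0.001,
                                         max_tries = 10000L) {
  for (t in seq_len(max_tries)) {
    f <- exp(runif(n_groups, log(floor), 0))
    f <- f / sum(f)
    if (min(f) >= floor) return(f)
  }
  abort("could not draw niche fractions above the 0.1% floor")
}

#' Functional-group specification of a community
#'
#' @param community A community tibble with groups assigned (see
#'   [assign_groups()]).
#' @return A tibble with one row per group: `group`, `niche_fraction`,
#'   `n_members`.
#' @export
group_spec <- function(community) {
  community <- as_community(community)
  if (is.null(community[["group"]])) abort("community has no group assignment")
  nf <- niche_fractions(community)
  members <- table(factor(community$group, levels = seq_along(nf)))
  tibble::tibble(
    group = seq_along(nf),
    niche_fraction = nf,
    n_members = as.integer(members)
  )
}

#' @rdname group_spec
#' @export
niche_fractions <- function(community) {
  nf <- attr(community, "niche_fractions")
  if (is.null(nf)) {
    if (is.null(community[["group"]])) return(1)
    g <- sort(unique(community$group))
    # fall back to the current relative group abundances
    nf <- vapply(g, function(gg) {
      sum(community$abundance[community$group == gg])
    }, numeric(1))
    nf <- nf / sum(nf)
  }
  nf
}

#' Validate a community table
#'
#' A community is a tibble with a character `population` column, a
#' non-negative integer `abundance` column, and optionally an integer `group`
#' column mapping every population to one functional group.
#'
#' @param x A data frame to validate.
#' @return The validated community as a tibble.
#' @export
as_community <- function(x) {
  if (!is.data.frame(x)) abort("a community must be a data frame")
  if (!all(c("population", "abundance") %in% names(x))) {
    abort("a community needs `population` and `abundance` columns")
  }
  if (nrow(x) < 1) abort("a community must contain at least one population")
  if (any(is.na(x$abundance)) || any(x$abundance < 0)) {
    abort("abundances must be non-negative")
  }
  if (any(x$abundance != as.integer(x$abundance))) {
    abort("abundances must be integer counts")
  }
  x <- tibble::as_tibble(x)
  x$abundance <- as.integer(x$abundance)
  if (!is.null(x[["group"]])) {
    if (any(is.na(x$group))) abort("every population must map to one group")
    x$group <- as.integer(x$group)
  }
  x
}

pop_labels <- function(n) sprintf("pop%0*d", max(3L, nchar(n)), seq_len(n))

# integer apportionment: floor + distribute the remainder by largest
# fractional part (ties broken by position, deterministically)
largest_remainder <- function(weights, total) {
  x <- weights / sum(weights) * total
  fl <- floor(x)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    idx <- ord[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

# raise zero counts to 1, taking from the largest counts
repair_minimum <- function(ab) {
  while (any(ab == 0L)) {
    i <- which.max(ab == 0L)
    j <- which.max(ab)
    ab[i] <- 1L
    ab[j] <- ab[j] - 1L
  }
  ab
}
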