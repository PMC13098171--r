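#' Specify a random interaction structure
#'
#' Describes how a random inter-group interaction matrix is drawn: the sign
#' of interactions, their common absolute strength, and the fraction of
#' eligible pairs that interact. Interactions are unidirectional: an
#' unordered pair is selected first and then given a random direction, so
#' `A[i, j] != 0` implies `A[j, i] == 0`.
#'
#' @param sign_mode `"positive"`, `"negative"`, or `"both"` (each selected
#'   interaction is +/- with probability 1/2).
#' @param strength Common absolute value of every interaction (> 0).
#' @param frequency Fraction of eligible pairs that interact, in (0, 1].
#' @param pairs What counts as an eligible pair: `"population"` (default;
#'   distinct unordered population pairs spanning two groups — the matrix is
#'   indexed by populations) or `"group"` (unordered group pairs; each
#'   selected group pair is realised by one random population from each
#'   group).
#' @return An `interaction_spec` object.
#' @examples
#' interaction_spec("negative", strength = 0.1, frequency = 0.1)
#' @export
interaction_spec <- function(sign_mode = c("positive", "negative", "both"),
                             strength, frequency,
                             pairs = c("population", "group")) {
  sign_mode <- match.arg(sign_mode)
  pairs <- match.arg(pairs)
  if (!is.numeric(strength) || strength <= 0) abort("`strength` must be > 0")
  if (!is.numeric(frequency) || frequency <= 0 || frequency > 1) {
    abort("`frequency` must be in (0, 1]")
  }
  structure(
    list(sign_mode = sign_mode, strength = strength, frequency = frequency,
         pairs = pairs),
    class = "interaction_spec"
  )
}

#' @export
print.interaction_spec <- function(x, ...) {
  cat(sprintf(
    "<interaction_spec> sign = %s, |strength| = %g, frequency = %g, pairs = %s\n",
    x$sign_mode, x$strength, x$frequency, x$pairs
  ))
  invisible(x)
}

#' Draw a random inter-group interaction matrix
#'
#' Samples `round(frequency * n_eligible_pairs)` unordered inter-group pairs
#' without replacement, assigns each a random direction, and sets the
#' corresponding entry to the signed strength. `A[i, j]` is the effect of
#' population `j` on the growth probability of population `i`; all entries
#' involve populations from different groups and every realised interaction
#' is unidirectional.
#'
#' @param community A community tibble with groups assigned.
#' @param spec An [interaction_spec()].
#' @param seed Optional integer seed.
#' @return A square numeric matrix with population IDs as dimnames.
#' @examples
#' comm <- generate_community(10, 100, seed = 1) |>
#'   assign_groups(2, seed = 1)
#' A <- generate_interaction_matrix(
#'   comm, interaction_spec("both", 0.1, 1), seed = 2
#' )
#' @export
generate_interaction_matrix <- function(community, spec, seed = NULL) {
  community <- as_community(community)
  if (is.null(community[["group"]])) {
    abort("interaction matrices need a community with functional groups")
  }
  stopifnot(inherits(spec, "interaction_spec"))
  if (!is.null(seed)) set.seed(seed)

  n <- nrow(community)
  g <- community$group
  A <- matrix(0, n, n, dimnames = list(community$population, community$population))

  if (spec$pairs == "population") {
    pr <- which(outer(g, g, "!="), arr.ind = TRUE)
    pr <- pr[pr[, 1] < pr[, 2], , drop = FALSE]  # unordered pairs
  } else {
    gs <- sort(unique(g))
    gp <- utils::combn(gs, 2)
    pr <- t(apply(gp, 2, function(pair) {
      c(resample(which(g == pair[1]), 1), resample(which(g == pair[2]), 1))
    }))
  }
  n_pairs <- nrow(pr)
  if (n_pairs == 0) abort("no eligible inter-group pairs (single group?)")
  n_sel <- round(spec$frequency * n_pairs)
  if (n_sel == 0) return(A)

  sel <- pr[resample(seq_len(n_pairs), n_sel), , drop = FALSE]
  flip <- runif(n_sel) < 0.5
  src <- ifelse(flip, sel[, 1], sel[, 2])  # acting population j
  dst <- ifelse(flip, sel[, 2], sel[, 1])  # affected population i
  sgn <- switch(spec$sign_mode,
    positive = rep(1, n_sel),
    negative = rep(-1, n_sel),
    both = ifelse(runif(n_sel) < 0.5, 1, -1)
  )
  A[cbind(dst, src)] <- sgn * spec$strength
  A
}

# sample() without the scalar-x surprise
resample <- function(x, size) x[sample.int(length(x), size)]

# internal: validate an interaction matrix against a community and convert
# to 0-based triplets for the C++ engine (zero entries dropped)
interaction_triplets <- function(A, community) {
  if (is.null(A)) {
    return(list(i = integer(0), j = integer(0), x = numeric(0)))
  }
  n <- nrow(community)
  if (!is.matrix(A) || nrow(A) != n || ncol(A) != n) {
    abort("interaction matrix must be square over the community's populations")
  }
  nz <- which(A != 0, arr.ind = TRUE)
  list(
    i = as.integer(nz[, 1] - 1L),
    j = as.integer(nz[, 2] - 1L),
    x = as.numeric(A[nz])
  )
}
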