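# Independent exact oracle for small two-population, one-scope communities.
#
# State: count of population 1 in a community of constant total size N.
# One dilution-growth cycle is composed of:
#   * a dilution kernel: binomial sampling with replacement down to
#     round(D * N) individuals, and
#   * a growth kernel: one individual added at a time with probability equal
#     to the current relative abundance (a Polya urn), back up to N.
# Both kernels are built by direct enumeration / dynamic programming, never
# by calling the simulator.

# P[m1 + 1, n1 + 1] = P(m1 survivors of pop 1 | n1 of N before dilution)
oracle_dilution_kernel <- function(N, target) {
  K <- matrix(0, target + 1, N + 1)
  for (n1 in 0:N) {
    K[, n1 + 1] <- stats::dbinom(0:target, target, n1 / N)
  }
  K
}

# P[j + 1, m1 + 1] = P(j of pop 1 at total N | m1 of `from` after dilution),
# adding one individual at a time proportional to current counts
oracle_growth_kernel <- function(from, N) {
  G <- matrix(0, N + 1, from + 1)
  for (m1 in 0:from) {
    # DP over intermediate totals
    v <- numeric(N + 1)
    v[m1 + 1] <- 1
    for (tot in from:(N - 1)) {
      nxt <- numeric(N + 1)
      for (j in 0:tot) {
        if (v[j + 1] == 0) next
        p1 <- j / tot
        nxt[j + 2] <- nxt[j + 2] + v[j + 1] * p1
        nxt[j + 1] <- nxt[j + 1] + v[j + 1] * (1 - p1)
      }
      v <- nxt
    }
    G[, m1 + 1] <- v
  }
  G
}

# full-cycle transition matrix T[j + 1, i + 1] = P(state j | state i)
oracle_cycle_matrix <- function(N, D) {
  target <- round(D * N)
  stopifnot(target >= 1)
  oracle_growth_kernel(target, N) %*% oracle_dilution_kernel(N, target)
}

# exact per-cycle state distribution and fixation probability; a state is
# fixed when one population strictly exceeds `threshold`, or only one
# population survives (j = 0 or j = N)
oracle_fixation_by_cycle <- function(N, D, start, n_cycles, threshold = 0.5) {
  T <- oracle_cycle_matrix(N, D)
  v <- numeric(N + 1)
  v[start + 1] <- 1
  fixed_states <- vapply(0:N, function(j) {
    j == 0 || j == N || j / N > threshold || (N - j) / N > threshold
  }, logical(1))
  out <- numeric(n_cycles)
  for (c in seq_len(n_cycles)) {
    v <- as.vector(T %*% v)
    out[c] <- sum(v[fixed_states])
  }
  out
}

# closed-form Polya-urn check used to validate the DP growth kernel:
# P(a additions of type 1 in s steps | m1, m2) =
#   choose(s, a) * rising(m1, a) * rising(m2, s - a) / rising(m1 + m2, s)
oracle_polya_pmf <- function(m1, m2, s, a) {
  rising <- function(x, k) if (k == 0) 1 else prod(x + 0:(k - 1))
  choose(s, a) * rising(m1, a) * rising(m2, s - a) / rising(m1 + m2, s)
}
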