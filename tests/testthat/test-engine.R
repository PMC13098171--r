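test_that("dilution hits the rounded target size and preserves composition on average", {
  comm <- generate_community(10, 1e4, seed = 1)
  d <- dilute(comm, 0.01, seed = 1)
  expect_equal(sum(d$abundance), 100L)
  expect_identical(d$population, comm$population)

  # a single population keeps 100% relative abundance
  solo <- tibble::tibble(population = "a", abundance = 500L)
  expect_equal(dilute(solo, 0.1, seed = 2)$abundance, 50L)

  # multinomial expectation: 50/50 community stays at 0.5 on average
  comm2 <- two_pop_community(5000, 5000)
  set.seed(42)
  reps <- 10000
  p1 <- vapply(seq_len(reps), function(i) {
    d <- dilute(comm2, 0.01)
    d$abundance[1] / sum(d$abundance)
  }, numeric(1))
  se <- stats::sd(p1) / sqrt(reps)
  expect_lt(abs(mean(p1) - 0.5), 3 * se)
})

test_that("a dilution target of zero empties the community", {
  comm <- generate_community(5, 100, seed = 1)
  d <- dilute(comm, 0.001, seed = 1)  # round(0.1) = 0
  expect_equal(sum(d$abundance), 0L)
})

test_that("growth probabilities follow relative abundances within scope", {
  comm <- two_pop_community(30, 70)
  p <- growth_probabilities(comm)
  expect_equal(p$probability, c(0.3, 0.7))

  # identity under a zero interaction matrix
  A0 <- matrix(0, 2, 2)
  expect_equal(growth_probabilities(comm, A0)$probability, c(0.3, 0.7))

  # direct arithmetic: p' = p + A p, clipped and renormalised
  comm5050 <- two_pop_community(50, 50)
  A <- matrix(c(0, 0.1, 0, 0), 2, 2, byrow = TRUE)  # A[1,2] = 0.1
  p2 <- growth_probabilities(comm5050, A)$probability
  expect_equal(p2, c(0.55 / 1.05, 0.5 / 1.05))

  # with groups, probabilities sum to 1 within each group
  cg <- generate_community(30, 3000, seed = 2) |>
    assign_groups(3, "homogeneous", seed = 2)
  pg <- growth_probabilities(cg)
  sums <- tapply(pg$probability, pg$group, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-12)
})

test_that("negative interaction pressure is clipped at zero", {
  comm <- two_pop_community(50, 50)
  A <- matrix(c(0, -2, 0, 0), 2, 2, byrow = TRUE)  # pushes p1 to 0.5 - 1 < 0
  p <- growth_probabilities(comm, A)$probability
  expect_equal(p, c(0, 1))
})

test_that("the growth phase restores the target exactly", {
  comm <- generate_community(20, 2000, seed = 3)
  d <- dilute(comm, 0.05, seed = 4)
  g <- growth_phase(d, target_total = 2000, seed = 5)
  expect_equal(sum(g$abundance), 2000L)

  # single population: deterministic refill
  solo <- tibble::tibble(population = "a", abundance = 100L)
  expect_equal(growth_phase(solo, target_total = 1e4, seed = 1)$abundance, 10000L)

  # grouped growth lands every surviving group exactly on its capacity
  cg <- generate_community(30, 3000, seed = 6) |>
    assign_groups(3, "homogeneous", seed = 6)
  dg <- dilute(cg, 0.1, seed = 7)
  eng <- driftsim:::engine_inputs(cg, 3000)
  gg <- growth_phase(dg, target_total = 3000, seed = 8)
  per_group <- tapply(gg$abundance, gg$group, sum)
  expect_equal(as.integer(per_group), eng$capacity)
})

test_that("relative abundance is a martingale across the growth phase", {
  # neutrality: E[final share] equals the initial share
  comm <- two_pop_community(10, 90)
  set.seed(99)
  reps <- 3000
  share <- vapply(seq_len(reps), function(i) {
    g <- growth_phase(comm, target_total = 1e4)
    g$abundance[1] / 1e4
  }, numeric(1))
  se <- stats::sd(share) / sqrt(reps)
  expect_lt(abs(mean(share) - 0.10), 3 * se)
})

test_that("trajectories complete, record every cycle, and are seed-deterministic", {
  comm <- generate_community(10, 1000, seed = 1)
  tr <- run_trajectory(comm, 0.01, n_cycles = 80, seed = 2)
  expect_equal(tr$status, "completed")
  expect_equal(nrow(tr$states), 80)
  expect_equal(tr$n_recorded, 80)
  expect_true(all(rowSums(tr$states) == 1000))

  tr2 <- run_trajectory(comm, 0.01, n_cycles = 80, seed = 2)
  expect_identical(tr$states, tr2$states)
  expect_identical(tr$final, tr2$final)
})

test_that("early stopping after absorption changes nothing observable", {
  comm <- generate_community(5, 200, seed = 3)
  a <- run_trajectory(comm, 0.05, n_cycles = 150, seed = 9, early_stop = TRUE)
  b <- run_trajectory(comm, 0.05, n_cycles = 150, seed = 9, early_stop = FALSE)
  expect_identical(a$states, b$states)
})

test_that("an unsustainable dilution collapses the trajectory at cycle 1", {
  comm <- generate_community(2, 100, seed = 1)
  tr <- run_trajectory(comm, 0.001, n_cycles = 10, seed = 1)
  expect_equal(tr$status, "collapsed")
  expect_equal(tr$collapse_cycle, 1L)
  expect_true(all(tr$states == 0L))
})

test_that("extinct groups lose their capacity and shrink the community", {
  # tiny groups under strong dilution go extinct; survivors still sit at
  # their own capacities and the total equals target minus lost capacity
  comm <- generate_community(20, 1000, seed = 5) |>
    assign_groups(5, "homogeneous", seed = 5)
  eng <- driftsim:::engine_inputs(comm, 1000)
  for (s in 1:5) {
    tr <- run_trajectory(comm, 0.01, n_cycles = 40, seed = s)
    if (tr$status != "completed") next
    for (cyc in c(10, 40)) {
      state <- tr$states[cyc, ]
      per_group <- tapply(state, comm$group, sum)
      gone <- per_group == 0
      expect_equal(as.integer(per_group[!gone]), eng$capacity[!gone])
    }
  }
})

test_that("neutral fixation is symmetric for equal founders", {
  comm <- two_pop_community(5, 5)
  winners <- vapply(1:400, function(s) {
    tr <- run_trajectory(comm, 0.5, n_cycles = 400, seed = s,
                         record = "final")
    which.max(tr$final)
  }, integer(1))
  phat <- mean(winners == 1)
  # binomial 99.9% band around 0.5 at n = 400
  expect_lt(abs(phat - 0.5), 3.29 * sqrt(0.25 / 400))
})

test_that("experiments stitch trajectories reproducibly, including in parallel", {
  comm <- generate_community(8, 400, seed = 2)
  ex1 <- run_experiment(comm, 0.05, n_trajectories = 6, n_cycles = 30, seed = 3)
  ex2 <- run_experiment(comm, 0.05, n_trajectories = 6, n_cycles = 30, seed = 3,
                        cores = 2)
  expect_identical(ex1$states, ex2$states)
  expect_identical(ex1$seeds, ex2$seeds)
  expect_equal(dim(ex1$states), c(30, 8, 6))
})
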