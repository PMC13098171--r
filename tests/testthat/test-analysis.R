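test_that("fixation requires strictly exceeding the threshold within the scope", {
  expect_equal(detect_fixation(two_pop_community(60, 40))$population, "popA")
  # boundary: 50% is not fixation
  expect_true(is.na(detect_fixation(two_pop_community(50, 50))$population))
  # 90% threshold
  expect_true(is.na(
    detect_fixation(two_pop_community(85, 15), fixation_threshold = 0.9)$population
  ))
  expect_equal(
    detect_fixation(two_pop_community(91, 9), fixation_threshold = 0.9)$population,
    "popA"
  )
})

test_that("a sole surviving population is fixed at any threshold; extinct scopes are not", {
  sole <- two_pop_community(25, 0)
  expect_equal(detect_fixation(sole, fixation_threshold = 1)$population, "popA")
  empty_scope <- two_pop_community(0, 0)
  res <- detect_fixation(empty_scope)
  expect_true(is.na(res$population))
  expect_true(res$extinct)
})

test_that("fixation is reported per functional group", {
  comm <- tibble::tibble(
    population = c("a", "b", "c", "d"),
    abundance = c(80L, 20L, 50L, 50L),
    group = c(1L, 1L, 2L, 2L)
  )
  res <- detect_fixation(comm)
  expect_equal(res$population, c("a", NA))
})

test_that("the worked success example: 95% all-group fixation by cycle 30", {
  # 100 trajectories of a 2-population scope; in 95 of them population 1
  # holds > 50% from cycle 30 on, in the other 5 the state stays 50/50
  nc <- 40; nt <- 100
  states <- array(0L, dim = c(nc, 2, nt))
  for (t in 1:nt) {
    if (t <= 95) {
      states[, 1, t] <- c(rep(50L, 29), rep(80L, nc - 29))
      states[, 2, t] <- c(rep(50L, 29), rep(20L, nc - 29))
    } else {
      states[, 1, t] <- 50L
      states[, 2, t] <- 50L
    }
  }
  sp <- success_profile(fake_experiment(states))
  expect_equal(sp$earliest_success_cycle, 30L)
  expect_equal(tidy(sp)$success_rate[29], 0)
  expect_equal(tidy(sp)$success_rate[30], 0.95)
})

test_that("a permanently extinct group blocks success under the default policy", {
  nc <- 5; nt <- 10
  states <- array(0L, dim = c(nc, 4, nt))
  states[, 1, ] <- 90L  # group 1 fixed everywhere
  states[, 2, ] <- 5L
  # group 2 (populations 3, 4) extinct in every trajectory
  ex <- fake_experiment(states, group = c(1L, 1L, 2L, 2L))
  expect_equal(tidy(success_profile(ex))$success_rate, rep(0, nc))
  # the permissive policy scores the surviving groups only
  expect_equal(
    tidy(success_profile(ex, extinct_groups = "ignore"))$success_rate,
    rep(1, nc)
  )
})

test_that("a single-population community succeeds immediately", {
  states <- array(100L, dim = c(3, 1, 1))
  sp <- success_profile(fake_experiment(states))
  expect_equal(sp$earliest_success_cycle, 1L)
})

test_that("success profiles are invariant to trajectory order", {
  comm <- generate_community(6, 300, seed = 1)
  ex <- run_experiment(comm, 0.05, n_trajectories = 12, n_cycles = 40, seed = 2)
  perm <- sample(12)
  ex_perm <- ex
  ex_perm$states <- ex$states[, , perm]
  expect_equal(
    tidy(success_profile(ex)),
    tidy(success_profile(ex_perm))
  )
})

test_that("success is monotone in cycles when fixation is absorbing", {
  comm <- generate_community(5, 100, seed = 7)
  ex <- run_experiment(comm, 0.1, n_trajectories = 40, n_cycles = 120, seed = 8)
  rate <- tidy(success_profile(ex))$success_rate
  expect_true(all(diff(rate) >= 0))
})

test_that("success rate never exceeds any group's fixation rate", {
  comm <- generate_community(20, 1000, seed = 9) |>
    assign_groups(3, "homogeneous", seed = 9)
  ex <- run_experiment(comm, 0.05, n_trajectories = 30, n_cycles = 60, seed = 10)
  sp <- tidy(success_profile(ex))
  for (cyc in c(10, 30, 60)) {
    gr <- group_rates(ex, at_cycle = cyc)
    expect_lte(sp$success_rate[cyc], min(gr$fixation_rate) / 100 + 1e-12)
  }
})

test_that("group rates count fixation and extinction separately", {
  nc <- 3; nt <- 4
  states <- array(0L, dim = c(nc, 4, nt))
  # group 1: sole survivor everywhere -> fixation 100%, extinction 0%
  states[, 1, ] <- 10L
  # group 2: extinct in half the trajectories, 50/50 split otherwise
  states[, 3, 1:2] <- 5L
  states[, 4, 1:2] <- 5L
  ex <- fake_experiment(states, group = c(1L, 1L, 2L, 2L))
  gr <- group_rates(ex)
  expect_equal(gr$fixation_rate, c(100, 0))
  expect_equal(gr$extinction_rate, c(0, 50))
})

test_that("at threshold 1 group fixation means exactly one survivor", {
  nc <- 2; nt <- 3
  states <- array(0L, dim = c(nc, 2, nt))
  states[, 1, 1] <- 10L                      # sole survivor
  states[, 1, 2] <- 99L; states[, 2, 2] <- 1L  # dominant but not alone
  states[, 1, 3] <- 5L; states[, 2, 3] <- 5L
  ex <- fake_experiment(states)
  gr <- group_rates(ex, fixation_threshold = 1)
  expect_equal(gr$fixation_rate, 100 / 3)
})

test_that("extinction is permanent under the engine's rules", {
  comm <- generate_community(10, 200, seed = 11) |>
    assign_groups(5, "homogeneous", seed = 11)
  ex <- run_experiment(comm, 0.05, n_trajectories = 20, n_cycles = 50, seed = 12)
  fa <- driftsim:::fixation_arrays(ex, 0.5)
  for (g in seq_along(fa$groups)) {
    for (t in seq_len(20)) {
      e <- fa$extinct[, g, t]
      if (any(e)) expect_true(all(e[which(e)[1]:length(e)]))
    }
  }
})

test_that("diversity metrics match closed forms", {
  unif <- tibble::tibble(population = letters[1:10], abundance = rep(7L, 10))
  m <- diversity_metrics(unif)
  expect_equal(m$richness, 10)
  expect_equal(m$shannon, log(10))
  expect_equal(m$pielou, 1)
  expect_equal(m$gini, 0)

  solo <- tibble::tibble(population = "a", abundance = 5L)
  ms <- diversity_metrics(solo)
  expect_equal(ms$shannon, 0)
  expect_equal(ms$pielou, 1)
  expect_equal(ms$gini, 0)

  skew <- two_pop_community(90, 10)
  expect_equal(diversity_metrics(skew)$shannon,
               -0.9 * log(0.9) - 0.1 * log(0.1))
  expect_error(diversity_metrics(two_pop_community(0, 0)), "empty")
})
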