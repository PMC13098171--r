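test_that("the shipped full-scale designs expand to their printed counts", {
  ct1 <- config_counts(scenario_config(scenario_path("scenario1")))
  expect_equal(ct1$n_combinations, 12)
  expect_equal(ct1$n_communities, 360)
  expect_equal(ct1$n_experiments, 5040)
  expect_equal(ct1$n_trajectories, 504000)

  ct2 <- config_counts(scenario_config(scenario_path("scenario2")))
  expect_equal(ct2$n_communities, 60)
  grid2 <- expand_config(scenario_path("scenario2"))
  expect_equal(length(unique(grid2$dilution_factor)), 9)

  # interaction grid: 3 signs x 5 strengths x 3 frequencies = 45 cells
  grid3 <- expand_config(scenario_path("scenario3_reduced"))
  expect_equal(nrow(grid3), 45)
})

test_that("a degenerate single-cell design expands to one experiment", {
  cfg <- list(
    richness = 10, size = 100, distribution = "uniform", replicates = 1,
    dilution_factors = 0.1
  )
  grid <- expand_config(cfg)
  expect_equal(nrow(grid), 1)
  expect_error(expand_config(list(richness = integer(), size = 10,
                                  dilution_factors = 0.1)), "non-empty")
})

test_that("expansion is deterministic and seeds are unique", {
  g1 <- expand_config(scenario_path("scenario1"))
  g2 <- expand_config(scenario_path("scenario1"))
  expect_identical(g1, g2)
  expect_false(any(duplicated(g1$experiment_seed)))
  expect_false(any(duplicated(g1$community_seed[!duplicated(g1$community_id)])))
})

test_that("seed splitting is collision-free for a million children", {
  s <- child_seeds(20260928, 0:(1e6 - 1))
  expect_false(any(duplicated(s)))
  expect_true(all(s >= 0 & s < 2^31))
  # different masters give different streams
  expect_false(identical(head(s, 100), child_seeds(1, 0:99)))
})

test_that("dilution factors outside (0, 1) are rejected", {
  expect_error(
    scenario_config(list(richness = 1, size = 10, dilution_factors = 1.2)),
    "dilution"
  )
})

test_that("a reduced scenario runs end to end with consistent outputs", {
  cfg <- scenario_config(list(
    name = "tiny", richness = 10, size = 200, distribution = "uniform",
    replicates = 2, dilution_factors = c(0.05, 0.1), n_trajectories = 8,
    n_cycles = 20, seed = 5
  ))
  out1 <- file.path(tempdir(), "tiny_run1")
  out2 <- file.path(tempdir(), "tiny_run2")
  unlink(c(out1, out2), recursive = TRUE)

  res1 <- run_scenario(cfg, out1)
  expect_equal(nrow(res1$summary), 4)
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_true(file.exists(file.path(out1, "summary.tsv")))
  expect_length(list.files(file.path(out1, "experiments")), 2 * 4)

  # byte-identical re-run
  run_scenario(cfg, out2)
  for (f in c("summary.tsv", list.files(file.path(out1, "experiments"),
                                        full.names = FALSE))) {
    p1 <- if (f == "summary.tsv") file.path(out1, f) else file.path(out1, "experiments", f)
    p2 <- if (f == "summary.tsv") file.path(out2, f) else file.path(out2, "experiments", f)
    expect_identical(readLines(p1), readLines(p2))
  }

  # resuming after losing one experiment reproduces it exactly
  lost <- list.files(file.path(out2, "experiments"), full.names = TRUE)[1:2]
  file.remove(lost)
  run_scenario(cfg, out2, resume = TRUE)
  for (f in list.files(file.path(out1, "experiments"))) {
    expect_identical(
      readLines(file.path(out1, "experiments", f)),
      readLines(file.path(out2, "experiments", f))
    )
  }
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("abundance tables and interaction matrices round-trip through text", {
  comm <- generate_community(6, 120, seed = 1) |>
    assign_groups(2, "homogeneous", seed = 1)
  p <- tempfile(fileext = ".tsv")
  write_abundance_table(list(c1 = comm, c2 = comm), p)
  back <- read_abundance_table(p)
  expect_equal(names(back), c("c1", "c2"))
  expect_equal(back$c1$abundance, comm$abundance)
  expect_equal(back$c1$group, comm$group)

  A <- generate_interaction_matrix(comm, interaction_spec("both", 0.5, 1), seed = 2)
  pa <- tempfile(fileext = ".csv")
  write_interaction_matrix(A, pa)
  expect_equal(read_interaction_matrix(pa), A)
})
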