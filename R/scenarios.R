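#' Load and validate a scenario configuration
#'
#' A scenario configuration describes a full grid of dilution-growth
#' experiments: community parameters (richness, size, abundance
#' distribution, replicate communities), dilution factors, trajectory
#' settings, analysis thresholds, optional functional-group configurations,
#' and an optional interaction grid. Configurations are YAML documents; the
#' package ships ready-made ones for three study designs at full scale and
#' at a reduced scale suitable for quick runs (see [scenario_path()]).
#'
#' @param x Path to a YAML file, or a list with the same fields.
#' @return A validated `scenario_config` object.
#' @examples
#' cfg <- scenario_config(scenario_path("scenario1"))
#' cfg$replicates
#' @export
scenario_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(
    name = "scenario", distribution = "uniform", replicates = 1L,
    n_trajectories = 100L, n_cycles = 200L, growth_rate = 0.01,
    fixation_thresholds = 0.5, success_threshold = 0.95,
    groups = NULL, interactions = NULL, seed = 1L
  )
  cfg <- modifyList(defaults, cfg)
  for (f in c("richness", "size", "dilution_factors")) {
    if (is.null(cfg[[f]]) || length(cfg[[f]]) == 0) {
      abort(paste0("scenario config needs a non-empty `", f, "`"))
    }
  }
  if (length(cfg$distribution) == 0) abort("`distribution` must be non-empty")
  if (any(cfg$dilution_factors <= 0) || any(cfg$dilution_factors >= 1)) {
    abort("all dilution factors must lie in (0, 1)")
  }
  if (!is.null(cfg$groups)) {
    cfg$groups <- lapply(cfg$groups, function(g) {
      stopifnot(!is.null(g$n_groups), !is.null(g$niche_mode))
      g
    })
  }
  if (!is.null(cfg$interactions)) {
    ia <- cfg$interactions
    stopifnot(!is.null(ia$sign_mode), !is.null(ia$strength),
              !is.null(ia$frequency))
  }
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  ct <- config_counts(x)
  cat(sprintf("<scenario_config> %s\n", x$name))
  cat(sprintf(
    "  %d parameter combinations, %d communities, %d experiments, %d trajectories\n",
    ct$n_combinations, ct$n_communities, ct$n_experiments, ct$n_trajectories
  ))
  invisible(x)
}

#' Path to a shipped scenario configuration
#'
#' @param name One of `"scenario1"`, `"scenario2"`, `"scenario3"`, or their
#'   `"_reduced"` variants.
#' @return The file path of the installed YAML configuration.
#' @export
scenario_path <- function(name) {
  p <- system.file("extdata", "scenarios", paste0(name, ".yml"),
                   package = "driftsim")
  if (p == "") abort(paste0("no shipped scenario called `", name, "`"))
  p
}

#' Expand a scenario configuration into an experiment grid
#'
#' Produces one row per fully-specified experiment: the cross of community
#' parameter combinations, replicate communities, group configurations (if
#' any), dilution factors, and interaction-grid cells (if any), in a fixed
#' deterministic order. Every community, group assignment, and experiment
#' receives its own child seed from the master seed via the collision-free
#' splitting rule ([child_seeds()]), so any subset of experiments can be
#' re-run bit-identically.
#'
#' @param config A `scenario_config` (or something [scenario_config()]
#'   accepts).
#' @return A tibble of experiment descriptors with a `counts` attribute;
#'   see [config_counts()].
#' @examples
#' grid <- expand_config(scenario_path("scenario1_reduced"))
#' nrow(grid)
#' @export
expand_config <- function(config) {
  cfg <- scenario_config(config)

  combos <- tidyr::expand_grid(
    richness = as.integer(cfg$richness),
    size = as.integer(cfg$size),
    distribution = cfg$distribution
  )
  combos$combo <- seq_len(nrow(combos))

  communities <- tidyr::expand_grid(
    combo = combos$combo,
    replicate = seq_len(cfg$replicates)
  )
  communities <- dplyr::left_join(communities, combos, by = "combo")
  communities$community_index <- seq_len(nrow(communities)) - 1L
  communities$community_id <- sprintf("comm%04d", communities$community_index + 1L)
  communities$community_seed <- child_seeds(cfg$seed, communities$community_index)

  group_grid <- if (is.null(cfg$groups)) {
    tibble::tibble(group_config = NA_integer_, n_groups = NA_integer_,
                   niche_mode = NA_character_)
  } else {
    tibble::tibble(
      group_config = seq_along(cfg$groups),
      n_groups = vapply(cfg$groups, function(g) as.integer(g$n_groups), integer(1)),
      niche_mode = vapply(cfg$groups, function(g) g$niche_mode, character(1))
    )
  }

  ia_grid <- if (is.null(cfg$interactions)) {
    tibble::tibble(sign_mode = NA_character_, strength = NA_real_,
                   frequency = NA_real_)
  } else {
    tidyr::expand_grid(
      sign_mode = cfg$interactions$sign_mode,
      strength = as.numeric(cfg$interactions$strength),
      frequency = as.numeric(cfg$interactions$frequency)
    )
  }

  grid <- tidyr::expand_grid(
    community_index = communities$community_index,
    group_config = group_grid$group_config,
    dilution_factor = as.numeric(cfg$dilution_factors),
    ia = seq_len(nrow(ia_grid))
  )
  grid <- dplyr::left_join(grid, communities, by = "community_index")
  grid <- dplyr::left_join(grid, group_grid, by = "group_config")
  grid <- dplyr::bind_cols(grid, ia_grid[grid$ia, ])
  grid$ia <- NULL

  n_comm <- nrow(communities)
  n_gc <- nrow(group_grid)
  # seed layout: [communities][community x group assignments][experiments]
  gc_index <- ifelse(is.na(grid$group_config), 1L, grid$group_config)
  grid$group_seed <- child_seeds(
    cfg$seed, n_comm + grid$community_index * n_gc + (gc_index - 1L)
  )
  grid$experiment_seed <- child_seeds(
    cfg$seed, n_comm + n_comm * n_gc + seq_len(nrow(grid)) - 1L
  )
  grid$experiment_id <- sprintf("exp%05d", seq_len(nrow(grid)))
  grid$n_trajectories <- as.integer(cfg$n_trajectories)
  grid$n_cycles <- as.integer(cfg$n_cycles)
  grid$growth_rate <- cfg$growth_rate

  out <- grid[, c(
    "experiment_id", "community_id", "richness", "size", "distribution",
    "replicate", "n_groups", "niche_mode", "dilution_factor", "sign_mode",
    "strength", "frequency", "n_trajectories", "n_cycles", "growth_rate",
    "community_seed", "group_seed", "experiment_seed"
  )]
  attr(out, "counts") <- list(
    n_combinations = nrow(combos),
    n_communities = n_comm,
    n_experiments = nrow(out),
    n_trajectories = sum(out$n_trajectories)
  )
  attr(out, "config") <- cfg
  out
}

#' Design counts of a scenario
#'
#' @param x A `scenario_config` or an expanded grid from [expand_config()].
#' @return A one-row tibble: number of parameter combinations, initial
#'   communities, experiments, and total trajectories.
#' @export
config_counts <- function(x) {
  ct <- attr(x, "counts")
  if (is.null(ct)) ct <- attr(expand_config(x), "counts")
  tibble::as_tibble(ct)
}

# materialise the initial community for one grid row
build_experiment_community <- function(row, cfg) {
  comm <- generate_community(
    row$richness, row$size, row$distribution, seed = row$community_seed,
    meanlog = cfg$meanlog %||% 0, sdlog = cfg$sdlog %||% 1
  )
  if (!is.na(row$n_groups)) {
    comm <- assign_groups(comm, row$n_groups, row$niche_mode,
                          seed = row$group_seed)
  }
  comm
}

#' Run a full scenario and persist its results
#'
#' Expands the configuration, generates every initial community, runs every
#' experiment with its own child seed, and writes delimited-text outputs
#' under `out_dir`: per-combination community abundance tables, one
#' per-experiment success-profile table (one row per fixation threshold and
#' cycle) and group-rate table, a one-row-per-experiment summary, and a JSON
#' manifest (config, fingerprint, seed, counts) sufficient to reproduce the
#' run. Because every experiment is independently seeded, re-running with
#' the same configuration is bit-identical at any `cores` setting, and a
#' partially-completed run can be resumed: experiments whose output files
#' already exist are skipped.
#'
#' @param config A scenario configuration (path, list, or
#'   `scenario_config`).
#' @param out_dir Output directory (created if needed).
#' @param cores Worker processes for experiments.
#' @param resume Skip experiments whose outputs already exist (default
#'   `TRUE`).
#' @param delim Output delimiter (TAB default).
#' @return Invisibly, a list with the expanded `grid`, the `summary`
#'   tibble, and the manifest path.
#' @export
run_scenario <- function(config, out_dir, cores = 1, resume = TRUE,
                         delim = "\t") {
  cfg <- scenario_config(config)
  grid <- expand_config(cfg)
  ext <- if (delim == ",") ".csv" else ".tsv"

  dir.create(file.path(out_dir, "communities"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "experiments"), showWarnings = FALSE)

  # one abundance table per parameter combination, replicates as columns
  comm_rows <- dplyr::distinct(
    grid, .data$community_id, .data$richness, .data$size,
    .data$distribution, .data$replicate, .data$community_seed
  )
  comb_key <- paste(comm_rows$richness, comm_rows$size, comm_rows$distribution)
  for (key in unique(comb_key)) {
    sub <- comm_rows[comb_key == key, ]
    comms <- lapply(seq_len(nrow(sub)), function(i) {
      generate_community(sub$richness[i], sub$size[i], sub$distribution[i],
                         seed = sub$community_seed[i],
                         meanlog = cfg$meanlog %||% 0,
                         sdlog = cfg$sdlog %||% 1)
    })
    names(comms) <- sub$community_id
    fn <- sprintf("communities_r%d_s%d_%s%s", sub$richness[1], sub$size[1],
                  sub$distribution[1], ext)
    write_abundance_table(comms, file.path(out_dir, "communities", fn),
                          delim = delim)
  }

  run_row <- function(i) {
    row <- grid[i, ]
    sf <- file.path(out_dir, "experiments",
                    paste0(row$experiment_id, "_success", ext))
    gf <- file.path(out_dir, "experiments",
                    paste0(row$experiment_id, "_groups", ext))
    if (resume && file.exists(sf)) {
      return(readr::read_delim(sf, delim = delim, show_col_types = FALSE,
                               progress = FALSE))
    }
    comm <- build_experiment_community(row, cfg)
    ia <- NULL
    if (!is.na(row$sign_mode)) {
      ia <- interaction_spec(row$sign_mode, row$strength, row$frequency)
    }
    ex <- run_experiment(
      comm, row$dilution_factor,
      n_trajectories = row$n_trajectories, n_cycles = row$n_cycles,
      growth_rate = row$growth_rate, interactions = ia,
      seed = row$experiment_seed
    )
    succ <- purrr::map_dfr(cfg$fixation_thresholds, function(th) {
      sp <- success_profile(ex, fixation_threshold = th,
                            success_threshold = cfg$success_threshold)
      dplyr::mutate(tidy(sp),
        experiment_id = row$experiment_id, fixation_threshold = th,
        .before = 1
      )
    })
    grp <- purrr::map_dfr(cfg$fixation_thresholds, function(th) {
      dplyr::mutate(group_rates(ex, fixation_threshold = th),
        experiment_id = row$experiment_id, fixation_threshold = th,
        .before = 1
      )
    })
    readr::write_delim(succ, sf, delim = delim)
    readr::write_delim(grp, gf, delim = delim)
    succ
  }

  idx <- seq_len(nrow(grid))
  success_tables <- if (cores > 1) {
    parallel::mclapply(idx, run_row, mc.cores = cores)
  } else {
    lapply(idx, run_row)
  }

  summary <- purrr::map_dfr(seq_along(success_tables), function(i) {
    st <- success_tables[[i]]
    st |>
      dplyr::group_by(.data$fixation_threshold) |>
      dplyr::summarise(
        earliest_success_cycle = {
          hit <- which(.data$success_rate >= cfg$success_threshold)
          if (length(hit)) .data$cycle[hit[1]] else NA_integer_
        },
        max_success_rate = max(.data$success_rate),
        .groups = "drop"
      ) |>
      dplyr::mutate(experiment_id = grid$experiment_id[i], .before = 1)
  })
  summary <- dplyr::left_join(
    summary,
    grid[, c("experiment_id", "community_id", "richness", "size",
             "distribution", "replicate", "n_groups", "niche_mode",
             "dilution_factor", "sign_mode", "strength", "frequency")],
    by = "experiment_id"
  )
  readr::write_delim(summary, file.path(out_dir, paste0("summary", ext)),
                     delim = delim)

  manifest <- list(
    name = cfg$name,
    config = unclass(cfg),
    config_fingerprint = fnv1a(yaml::as.yaml(unclass(cfg))),
    counts = attr(grid, "counts"),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("driftsim"))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(grid = grid, summary = summary, manifest = manifest_path))
}
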