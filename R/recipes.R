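#' Canned in-silico experiments
#'
#' Each recipe bundles a full multi-replicate simulated experiment: construct
#' generation, runs, readouts, replicate aggregation, and a provenance
#' manifest (package version, full configuration, and every per-run seed), so
#' every output is reconstructible from the manifest alone.  Per-run seeds
#' are derived deterministically from the root `seed`.
#'
#' Available recipes:
#' * `influx_feedback` — elongation progress and late-run pPSM density with
#'   progenitor influx on versus off.
#' * `repulsion_sweep` — one-axis PSM-PSM repulsion slice, regime labels and
#'   transition location.
#' * `perturbation_readouts` — boundary pressure, axial pushing force and PD
#'   lateral flux for control, pulled, compressed and pPSM-deleted groups.
#' * `length_recovery` — axis-length recovery after posterior-graded
#'   stretch/compression, plus the global-strain elongation-extent groups.
#'
#' @param name recipe name.
#' @param n_replicates seeds per group (`NULL` = recipe default).
#' @param seed root seed.
#' @param overrides named list overriding recipe configuration entries
#'   (`n_iterations`, `influx_rate`, `strain`, `apply_at`, `record_every`,
#'   `deletion_fraction`, `points`, `sweep_replicates`).
#' @param out_dir optional directory; tables are written as CSV and the
#'   manifest as YAML.
#' @return List with `tables` (named list of data.frames), `results`
#'   (recipe-specific numbers), and `manifest`.
#' @export
run_recipe <- function(name = c("influx_feedback", "repulsion_sweep",
                                "perturbation_readouts", "length_recovery"),
                       n_replicates = NULL, seed = 1L, overrides = list(),
                       out_dir = NULL) {
  name <- match.arg(name)
  bundle <- switch(name,
    influx_feedback = recipe_influx_feedback(n_replicates, seed, overrides),
    repulsion_sweep = recipe_repulsion_sweep(n_replicates, seed, overrides),
    perturbation_readouts =
      recipe_perturbation_readouts(n_replicates, seed, overrides),
    length_recovery = recipe_length_recovery(n_replicates, seed, overrides))
  bundle$manifest$recipe <- name
  bundle$manifest$package_version <- as.character(packageVersion("axisim"))
  bundle$manifest$root_seed <- as.integer(seed)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir, name)
  bundle
}

recipe_config <- function(defaults, overrides) {
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

recipe_seed <- function(seed, group, rep) {
  as.integer((as.numeric(seed) %% 1e5) * 10000 + group * 500 + rep)
}

run_group <- function(cfg, seed, group, n, perturbation = NULL,
                      influx_rate = cfg$influx_rate) {
  lapply(seq_len(n), function(r) {
    s <- recipe_seed(seed, group, r)
    tc <- build_construct(2, seed = s)
    run_simulation(tc, mechanics_params(), n_iterations = cfg$n_iterations,
                   influx_rate = influx_rate, perturbation = perturbation,
                   record_every = cfg$record_every, seed = s)
  })
}

recipe_influx_feedback <- function(n, seed, overrides) {
  cfg <- recipe_config(list(n_replicates = if (is.null(n)) 20 else n,
                            n_iterations = 6000, influx_rate = 0.3,
                            record_every = 200, smooth_bin = 50), overrides)
  on_runs <- run_group(cfg, seed, 1, cfg$n_replicates)
  off_runs <- run_group(cfg, seed, 2, cfg$n_replicates, influx_rate = 0)
  elong <- function(runs, cond) {
    tabs <- lapply(runs, function(tr)
      bin_series(tr$length_series - tr$length_series[1],
                 "elongation_progress", cfg$smooth_bin))
    agg <- aggregate_replicates(tabs)
    agg$condition <- cond
    agg
  }
  dens <- function(runs, cond) {
    tabs <- lapply(runs, density_profile)
    agg <- aggregate_replicates(tabs)
    agg$condition <- cond
    agg
  }
  ppsm_mean <- function(runs) {
    mean(vapply(runs, function(tr) {
      d <- density_profile(tr)
      mean(d$mean[d$region == "pPSM"])
    }, numeric(1)))
  }
  final_elong <- function(runs)
    vapply(runs, function(tr)
      tr$length_series[cfg$n_iterations] - tr$length_series[1], numeric(1))
  list(
    tables = list(
      elongation = rbind(elong(on_runs, "influx_on"),
                         elong(off_runs, "influx_off")),
      density = rbind(dens(on_runs, "influx_on"),
                      dens(off_runs, "influx_off"))),
    results = list(
      ppsm_density_on = ppsm_mean(on_runs),
      ppsm_density_off = ppsm_mean(off_runs),
      elongation_on = mean(final_elong(on_runs)),
      elongation_off = mean(final_elong(off_runs))),
    manifest = list(config = cfg,
                    seeds = list(influx_on = vapply(on_runs, `[[`, 1L, "seed"),
                                 influx_off = vapply(off_runs, `[[`, 1L,
                                                     "seed"))))
}

recipe_repulsion_sweep <- function(n, seed, overrides) {
  cfg <- recipe_config(list(points = 17, sweep_replicates = if (is.null(n)) 5
                            else n, n_iterations = 4000), overrides)
  grid <- generate_grid(points_per_axis = cfg$points)
  res <- run_sweep(grid, replicates = cfg$sweep_replicates,
                   n_iterations = cfg$n_iterations, seed = seed)
  tr <- find_transition(res)
  list(tables = list(sweep = res),
       results = list(transition_scaled = as.numeric(tr),
                      interval = attr(tr, "interval"),
                      monotone = attr(tr, "monotone")),
       manifest = list(config = cfg, seeds = unique(res$seed)))
}

recipe_perturbation_readouts <- function(n, seed, overrides) {
  cfg <- recipe_config(list(n_replicates = if (is.null(n)) 10 else n,
                            n_iterations = 6000, influx_rate = 0.3,
                            record_every = 100, strain = 0.125,
                            apply_at = 1000, deletion_fraction = 0.5,
                            magnitude_parameter = 80), overrides)
  groups <- list(
    control = NULL,
    pulled = perturbation("GRADED_STRAIN", strain = cfg$strain,
                          apply_at_iteration = cfg$apply_at,
                          magnitude_parameter = cfg$magnitude_parameter),
    compressed = perturbation("GRADED_STRAIN", strain = -cfg$strain,
                              apply_at_iteration = cfg$apply_at,
                              magnitude_parameter = cfg$magnitude_parameter),
    deleted = perturbation("DELETE_PPSM",
                           deletion_fraction = cfg$deletion_fraction,
                           apply_at_iteration = cfg$apply_at))
  runs <- lapply(seq_along(groups), function(g)
    run_group(cfg, seed, g, cfg$n_replicates, perturbation = groups[[g]]))
  names(runs) <- names(groups)
  agg <- function(fn, ...) {
    tabs <- lapply(names(runs), function(g) {
      t <- aggregate_replicates(lapply(runs[[g]], fn, ...))
      t$condition <- g
      t
    })
    do.call(rbind, tabs)
  }
  list(
    tables = list(
      pressure = agg(function(tr) boundary_pressure(tr, from = cfg$apply_at)),
      force = agg(axial_push_force),
      flux = agg(pd_lateral_flux)),
    results = list(),
    manifest = list(config = cfg,
                    seeds = lapply(runs, function(rs)
                      vapply(rs, `[[`, 1L, "seed"))))
}

recipe_length_recovery <- function(n, seed, overrides) {
  cfg <- recipe_config(list(n_replicates = if (is.null(n)) 40 else n,
                            extent_replicates = 25,
                            n_iterations = 6000, influx_rate = 0.3,
                            record_every = 500, strain = 0.125,
                            apply_at = 1000,
                            magnitude_parameter = 80), overrides)
  graded <- function(s) perturbation("GRADED_STRAIN", strain = s,
                                     apply_at_iteration = cfg$apply_at,
                                     magnitude_parameter =
                                       cfg$magnitude_parameter)
  global <- function(s) perturbation("GLOBAL_STRAIN", strain = s,
                                     apply_at_iteration = cfg$apply_at)
  groups <- list(control = NULL, pulled = graded(cfg$strain),
                 compressed = graded(-cfg$strain))
  runs <- lapply(seq_along(groups), function(g)
    run_group(cfg, seed, g, cfg$n_replicates, perturbation = groups[[g]]))
  names(runs) <- names(groups)

  lengths_at <- function(tr, it) {
    i0 <- tr$post_perturbation_snapshot
    at_pert <- if (!is.na(i0)) snapshot_axis_length(tr, i0)
               else tr$length_series[cfg$apply_at]
    c(at_perturbation = at_pert, final = tr$length_series[it])
  }
  lens <- lapply(runs, function(rs)
    t(vapply(rs, lengths_at, numeric(2), it = cfg$n_iterations)))
  gap <- function(g, col) abs(mean(lens[[g]][, col]) -
                              mean(lens$control[, col]))

  # global-strain elongation-extent groups (no influx)
  ext_groups <- list(control = NULL, stretched = global(cfg$strain),
                     compressed = global(-cfg$strain))
  ext_runs <- lapply(seq_along(ext_groups), function(g)
    run_group(cfg, seed, 10 + g, cfg$extent_replicates,
              perturbation = ext_groups[[g]], influx_rate = 0))
  names(ext_runs) <- names(ext_groups)
  extents <- lapply(ext_runs, function(rs)
    vapply(rs, elongation_extent, numeric(1),
           from_iteration = cfg$apply_at))

  length_tab <- do.call(rbind, lapply(names(runs), function(g) {
    d <- as.data.frame(lens[[g]])
    d$condition <- g
    d$seed <- vapply(runs[[g]], `[[`, 1L, "seed")
    d
  }))
  extent_tab <- do.call(rbind, lapply(names(ext_runs), function(g)
    data.frame(condition = g, extent = extents[[g]],
               seed = vapply(ext_runs[[g]], `[[`, 1L, "seed"))))

  list(
    tables = list(lengths = length_tab, extents = extent_tab),
    results = list(
      gap_at_perturbation = c(pulled = gap("pulled", "at_perturbation"),
                              compressed = gap("compressed",
                                               "at_perturbation")),
      gap_final = c(pulled = gap("pulled", "final"),
                    compressed = gap("compressed", "final")),
      extent_means = vapply(extents, mean, numeric(1))),
    manifest = list(config = cfg,
                    seeds = c(lapply(runs, function(rs)
                                vapply(rs, `[[`, 1L, "seed")),
                              lapply(ext_runs, function(rs)
                                vapply(rs, `[[`, 1L, "seed")))))
}

write_bundle <- function(bundle, out_dir, name) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle$tables)) {
    write.csv(bundle$tables[[nm]],
              file.path(out_dir, paste0(name, "_", nm, ".csv")),
              row.names = FALSE)
  }
  yaml::write_yaml(rapply(bundle$manifest, unclass, how = "replace"),
                   file.path(out_dir, paste0(name, "_manifest.yaml")))
  invisible(out_dir)
}
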