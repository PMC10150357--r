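#' Advance a simulation
#'
#' Runs the full per-MCS loop: motility directions are redrawn every
#' `motility_recalc_interval` MCS, one Monte Carlo sweep is performed, the
#' lifecycle pass draws division and death events, the clock advances, and
#' the phenotype composition is recorded every `composition_cadence` MCS.
#' Stops early (with the extinction flag set) if the cancer population dies
#' out.
#'
#' @param sim A `"cpm_sim"`.
#' @param n_mcs Number of MCS to advance.
#' @param lifecycle Run division/death (default TRUE)?
#' @return `sim`, invisibly; query [sim_info()] for status.
#' @export
advance_simulation <- function(sim, n_mcs, lifecycle = TRUE) {
  stopifnot(inherits(sim, "cpm_sim"), n_mcs >= 0)
  cpp_sim_run(sim$ptr, as.numeric(n_mcs),
              sim$config$composition_cadence, isTRUE(lifecycle))
  invisible(sim)
}

#' Event log of a simulation
#'
#' @param sim A `"cpm_sim"`.
#' @return Data frame with columns `time_mcs`, `event` (`"division"`,
#'   `"death"`, or `"mechanical_death"`), `cell_id`, `phenotype_id`, `x`,
#'   `y`, `z`, `radius` (distance of the event from the box center), and
#'   `mutated` (divisions only: did a daughter's phenotype change).
#' @export
sim_events <- function(sim) {
  ev <- cpp_sim_events(sim$ptr)
  kinds <- c("division", "death", "mechanical_death")
  data.frame(
    time_mcs = ev$time_mcs,
    event = kinds[ev$kind],
    cell_id = ev$cell_id,
    phenotype_id = ifelse(ev$adh_index >= 0,
                          12L * ev$adh_index + ev$mot_index + 1L, NA_integer_),
    x = ev$x, y = ev$y, z = ev$z, radius = ev$radius,
    mutated = ev$mutated == 1L
  )
}

#' Composition series of a simulation
#'
#' The sampled counts of live (non-dying) cancer cells per phenotype, the
#' substrate for all evolution-trajectory analysis.
#'
#' @param sim A `"cpm_sim"`.
#' @return Data frame with columns `time_mcs`, `adhesion`, `motility`,
#'   `count` (all 144 phenotypes at every sampled time).
#' @export
sim_composition <- function(sim) {
  co <- cpp_sim_composition(sim$ptr)
  data.frame(
    time_mcs = co$time_mcs,
    adhesion = 10 * co$adh_index,
    motility = 10 * co$mot_index,
    count = co$count
  )
}

#' Run a full simulation
#'
#' Initializes the tissue from `config`, relaxes the cubic tiling with
#' `relax_mcs` plain sweeps (no lifecycle, clock frozen), then advances the
#' run loop for `run_length` MCS.  Optionally writes the composition series,
#' event log, lattice snapshots, and a JSON manifest to `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return A list of class `"cpm_run"` with elements `composition`,
#'   `events`, `manifest`, `status` (`"completed"` or `"extinct"`), and the
#'   live `sim` handle.
#' @export
run_simulation <- function(config, out_dir = NULL) {
  sim <- initialize_tissue(config)
  if (config$relax_mcs > 0) monte_carlo_sweep(sim, config$relax_mcs)

  snap_paths <- character(0)
  if (!is.null(out_dir) && config$snapshot_cadence > 0) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    remaining <- config$run_length
    while (remaining > 0) {
      chunk <- min(config$snapshot_cadence, remaining)
      advance_simulation(sim, chunk)
      remaining <- remaining - chunk
      info <- cpp_sim_info(sim$ptr)
      p <- file.path(out_dir, sprintf("snapshot_t%08d.vtk", as.integer(info$time)))
      write_snapshot_vtk(sim, p)
      snap_paths <- c(snap_paths, p)
      if (info$extinct) break
    }
  } else {
    advance_simulation(sim, config$run_length)
  }

  info <- cpp_sim_info(sim$ptr)
  status <- if (info$extinct) "extinct" else "completed"
  frag <- sim_fragments(sim)
  manifest <- list(
    config = unclass(config),
    package_version = as.character(packageVersion("spheroidevo")),
    status = status,
    final_time_mcs = info$time,
    n_cancer_final = info$n_cancer,
    attempts = info$attempts,
    accepts = info$accepts,
    fragmented_cells = sum(frag$components > 1),
    snapshots = snap_paths
  )
  out <- structure(
    list(composition = sim_composition(sim), events = sim_events(sim),
         manifest = manifest, status = status, sim = sim),
    class = "cpm_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(out$composition, file.path(out_dir, "composition.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(out$events, file.path(out_dir, "events.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cen <- composition_centroids(out$composition)
    if (nrow(cen) > 0)
      write.table(cen, file.path(out_dir, "centroids.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.cpm_run <- function(x, ...) {
  cat(sprintf("<cpm_run: %s at t=%g MCS, %g cancer cells, %d events>\n",
              x$status, x$manifest$final_time_mcs, x$manifest$n_cancer_final,
              nrow(x$events)))
  invisible(x)
}

#' Deterministic per-run seed derivation
#'
#' Mixes the master seed with the sweep condition (period) and replicate
#' index into an integer below 2^31, so that sweep runs are independent yet
#' reproducible from the master seed alone.
#'
#' @param master_seed Integer master seed.
#' @param period Fluctuation period of the condition (0 for the constant
#'   control).
#' @param replicate Replicate index.
#' @return A positive integer seed.
#' @export
derive_seed <- function(master_seed, period, replicate) {
  h <- (as.numeric(master_seed) * 1000003 + as.numeric(period) * 7919 +
          as.numeric(replicate) * 104729) %% 2147483629
  as.integer(h + 1)
}

#' Period sweep with replicates
#'
#' Runs `replicates` simulations per nutrient fluctuation period in
#' `periods` (orbiting sink) plus, optionally, a constant-environment
#' control group (static sink, recorded as period 0), with per-run seeds
#' derived from the master seed.  Each run is summarized by its run-mean
#' evolution speed and spread; failures of individual runs are recorded and
#' the sweep continues.
#'
#' @param base_config A [run_config()] used for every run (its nutrient mode
#'   and period are overridden per condition).
#' @param periods Numeric vector of fluctuation periods T in MCS.
#' @param replicates Replicates per condition.
#' @param master_seed Master seed (default: the base configuration's seed).
#' @param include_constant Include the constant control group (default TRUE).
#' @param speed_window Smoothing window (MCS) for the speed estimator.
#' @param burn_in_frac Fraction of early samples excluded from run means.
#' @param out_dir Optional directory: per-run outputs and the summary table
#'   are written beneath it.
#' @return Data frame with one row per run: `period_mcs` (0 = constant
#'   control), `replicate`, `rng_seed`, `status`, `mean_speed`,
#'   `mean_spread`, `n_samples`.
#' @export
sweep_periods <- function(base_config, periods, replicates,
                          master_seed = base_config$rng_seed,
                          include_constant = TRUE,
                          speed_window = 10000, burn_in_frac = 0.1,
                          out_dir = NULL) {
  stopifnot(inherits(base_config, "run_config"), replicates >= 1)
  conds <- c(if (include_constant) 0, periods)
  rows <- list()
  for (Tp in conds) {
    for (rep_i in seq_len(replicates)) {
      cfg <- base_config
      cfg$rng_seed <- derive_seed(master_seed, Tp, rep_i)
      cfg$replicate_id <- rep_i
      if (Tp > 0) {
        cfg$nutrient_mode <- "orbiting"
        cfg$orbit_period <- Tp
      } else {
        cfg$nutrient_mode <- "static"
      }
      run_dir <- if (!is.null(out_dir))
        file.path(out_dir, sprintf("T%g_rep%d", Tp, rep_i)) else NULL
      row <- tryCatch({
        res <- run_simulation(cfg, out_dir = run_dir)
        summ <- summarize_run(res$composition, window_mcs = speed_window,
                              burn_in_frac = burn_in_frac)
        data.frame(period_mcs = Tp, replicate = rep_i,
                   rng_seed = cfg$rng_seed, status = res$status,
                   mean_speed = summ$mean_speed,
                   mean_spread = summ$mean_spread,
                   n_samples = nrow(summ$centroids))
      }, error = function(e) {
        data.frame(period_mcs = Tp, replicate = rep_i,
                   rng_seed = cfg$rng_seed,
                   status = paste("error:", conditionMessage(e)),
                   mean_speed = NA_real_, mean_spread = NA_real_,
                   n_samples = 0L)
      })
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(out, file.path(out_dir, "sweep_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Write a lattice snapshot as legacy VTK structured points
#'
#' Emits an ASCII VTK file with one scalar per voxel, loadable by ParaView
#' and similar viewers, for visual inspection of the spheroid.
#'
#' @param sim A `"cpm_sim"`.
#' @param path Output `.vtk` path.
#' @param field `"cell_id"`, `"phenotype_id"` (healthy voxels: 0), or
#'   `"nutrient"` (the availability of each voxel's cell at the current
#'   time, for visual parity with availability-colored renderings).
#' @return `path`, invisibly.
#' @export
write_snapshot_vtk <- function(sim, path,
                               field = c("cell_id", "phenotype_id",
                                         "nutrient")) {
  field <- match.arg(field)
  st <- sim_state(sim)
  L <- dim(st$spins)[1]
  vals <- as.vector(st$spins)
  vtype <- "int"
  if (field == "phenotype_id") {
    cells <- st$cells
    pid <- ifelse(cells$type == 1L,
                  12L * cells$adh_index + cells$mot_index + 1L, 0L)
    vals <- pid[vals]
  } else if (field == "nutrient") {
    env <- config_nutrient_env(sim$config)
    cells <- st$cells
    com <- cbind(cells$com_x, cells$com_y, cells$com_z)
    avail <- rep(NA_real_, nrow(cells))
    ok <- cells$alive
    avail[ok] <- nutrient_at(env, com[ok, , drop = FALSE], st$time)
    vals <- round(avail[vals], 6)
    vtype <- "float"
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("spheroidevo snapshot t=%g", st$time),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", L, L, L),
               "ORIGIN 0 0 0",
               "SPACING 1 1 1",
               sprintf("POINT_DATA %d", L^3),
               sprintf("SCALARS %s %s 1", field, vtype),
               "LOOKUP_TABLE default"), con)
  writeLines(format(vals, trim = TRUE), con)
  invisible(path)
}
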