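#' Simulation run configuration
#'
#' Bundles every parameter of a spheroid run: lattice size, Hamiltonian
#' couplings, lifecycle rates and gates, nutrient environment, mutation rule,
#' initialization, run length, output cadence, and RNG seed.  Defaults are
#' the desk-scale profile (64-voxel box); the production profile uses a
#' 200-voxel box, 580 kMCS, and 21 replicates per condition and is intended
#' for cluster runs (see the package vignette).
#'
#' @param grid_side Lattice side length L in voxels (1 voxel ~ 1 um); the
#'   lattice is periodic in all three axes.
#' @param seed_radius Radius (voxels) of the initial spherical cancer seed.
#' @param healthy_block Side of the cubic blocks tiling the healthy tissue at
#'   initialization; must divide `grid_side`.
#' @param target_volume Target cell volume V0 in voxels (500).
#' @param volume_coupling Volume elasticity coupling (8).
#' @param target_surface Target cell surface S0 in boundary faces (400).
#' @param surface_coupling Surface elasticity coupling (6).
#' @param temperature Metropolis temperature T_MC (55).
#' @param central_coupling Coupling of cancer cells to the central potential
#'   (-70 as printed; its magnitude acts as a constant force toward the box
#'   center).
#' @param motility_recalc_interval Interval (MCS) at which every cell's
#'   preferred motility direction is redrawn uniformly on the sphere (100).
#' @param adhesion_healthy Adhesion (bond) strength per contact face for any
#'   pair involving a healthy cell (default 50, the mid-range cancer value);
#'   contact energy is the negative of the bond strength, so adhesion is
#'   never repulsive.
#' @param healthy_motility Motility strength of healthy cells (default 0:
#'   motility is a cancer phenotype axis).
#' @param neighborhood Lattice neighborhood for flip candidates and
#'   face/contact-area counting: 6 (von Neumann, default) or 26 (Moore).
#' @param division_age_min Minimum age (MCS) before a cancer cell may divide
#'   (2000).
#' @param death_age_min Minimum age (MCS) before a cancer cell may die (4000).
#' @param division_volume_fraction Fraction of `target_volume` a cell must
#'   exceed to divide (0.9, i.e. 450 voxels).
#' @param max_division_rate Division probability per MCS at full nutrient
#'   (0.005).
#' @param max_death_rate Death probability per MCS at zero nutrient (0.001).
#' @param dependency_mode `"linear"` (rates scale with local nutrient
#'   availability) or `"none"` (constant rates at the maxima).
#' @param mutation_probability Per-division phenotype mutation probability
#'   (0.04).
#' @param mutation_boundary Edge rule for mutation steps leaving the grid:
#'   `"abort"` or `"reflect"`.
#' @param nutrient_mode `"static"` or `"orbiting"` sink.
#' @param orbit_amplitude Orbit radius A of the sink in voxels (50).
#' @param orbit_period Orbit period T in MCS (used in orbiting mode).
#' @param decay_radius Distance at which nutrient availability saturates at
#'   1; defaults to `grid_side / 2` so the tumor rim sits near maximal
#'   availability.
#' @param initial_adhesion,initial_motility Seed phenotype (50, 50).
#' @param run_length Simulated MCS of the main run.
#' @param composition_cadence Interval (MCS) between composition samples.
#' @param snapshot_cadence Interval (MCS) between lattice snapshots written
#'   by [run_simulation()] when an output directory is given; 0 disables.
#' @param relax_mcs Burn-in sweeps (without lifecycle or clock) that relax
#'   the initial cubic tiling into rounded cells.
#' @param rng_seed Integer seed; a run is bit-reproducible from its
#'   configuration and seed.
#' @param replicate_id Identifier carried into outputs.
#' @return An object of class `"run_config"` (a validated named list).
#' @export
run_config <- function(grid_side = 64,
                       seed_radius = grid_side / 4,
                       healthy_block = 8,
                       target_volume = 500,
                       volume_coupling = 8,
                       target_surface = 400,
                       surface_coupling = 6,
                       temperature = 55,
                       central_coupling = -70,
                       motility_recalc_interval = 100,
                       adhesion_healthy = 50,
                       healthy_motility = 0,
                       neighborhood = 6,
                       division_age_min = 2000,
                       death_age_min = 4000,
                       division_volume_fraction = 0.9,
                       max_division_rate = 0.005,
                       max_death_rate = 0.001,
                       dependency_mode = c("linear", "none"),
                       mutation_probability = 0.04,
                       mutation_boundary = c("abort", "reflect"),
                       nutrient_mode = c("static", "orbiting"),
                       orbit_amplitude = 50,
                       orbit_period = 10000,
                       decay_radius = grid_side / 2,
                       initial_adhesion = 50,
                       initial_motility = 50,
                       run_length = 20000,
                       composition_cadence = 100,
                       snapshot_cadence = 0,
                       relax_mcs = 50,
                       rng_seed = 1,
                       replicate_id = 1) {
  cfg <- list(
    grid_side = as.integer(grid_side), seed_radius = seed_radius,
    healthy_block = as.integer(healthy_block),
    target_volume = target_volume, volume_coupling = volume_coupling,
    target_surface = target_surface, surface_coupling = surface_coupling,
    temperature = temperature, central_coupling = central_coupling,
    motility_recalc_interval = as.integer(motility_recalc_interval),
    adhesion_healthy = adhesion_healthy, healthy_motility = healthy_motility,
    neighborhood = as.integer(neighborhood),
    division_age_min = division_age_min, death_age_min = death_age_min,
    division_volume_fraction = division_volume_fraction,
    max_division_rate = max_division_rate, max_death_rate = max_death_rate,
    dependency_mode = match.arg(dependency_mode),
    mutation_probability = mutation_probability,
    mutation_boundary = match.arg(mutation_boundary),
    nutrient_mode = match.arg(nutrient_mode),
    orbit_amplitude = orbit_amplitude, orbit_period = orbit_period,
    decay_radius = decay_radius,
    initial_adhesion = initial_adhesion, initial_motility = initial_motility,
    run_length = run_length,
    composition_cadence = as.integer(composition_cadence),
    snapshot_cadence = as.integer(snapshot_cadence),
    relax_mcs = as.integer(relax_mcs),
    rng_seed = as.integer(rng_seed), replicate_id = replicate_id
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg A `"run_config"` list.
#' @return `cfg`, invisibly checked; errors on invalid values.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  with(cfg, {
    if (grid_side < 8) stop("grid_side must be at least 8", call. = FALSE)
    if (grid_side %% healthy_block != 0)
      stop("healthy_block must divide grid_side", call. = FALSE)
    if (seed_radius <= 0 || seed_radius >= grid_side / 2)
      stop("seed_radius must be positive and below half the box", call. = FALSE)
    if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
    if (target_volume <= 0 || target_surface <= 0)
      stop("target volume and surface must be positive", call. = FALSE)
    if (!neighborhood %in% c(6L, 26L))
      stop("neighborhood must be 6 or 26", call. = FALSE)
    for (r in c(max_division_rate, max_death_rate, mutation_probability))
      if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
    if (division_age_min < 0 || death_age_min < 0)
      stop("age thresholds must be nonnegative", call. = FALSE)
    if (nutrient_mode == "orbiting" && orbit_period <= 0)
      stop("orbiting mode requires a positive orbit_period", call. = FALSE)
    if (decay_radius <= 0) stop("decay_radius must be positive", call. = FALSE)
    invisible(NULL)
  })
  # seed phenotype must sit on the grid
  phenotype(cfg$initial_adhesion, cfg$initial_motility)
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config: L=%d, %s nutrient (%s rates), seed phenotype (%g, %g), %g MCS, seed %d>\n",
    x$grid_side, x$nutrient_mode, x$dependency_mode,
    x$initial_adhesion, x$initial_motility, x$run_length, x$rng_seed))
  invisible(x)
}

#' Read / write run configurations as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a [run_config()];
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A [run_config()] to serialize.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
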