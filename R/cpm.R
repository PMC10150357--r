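#' Create a simulation from a configuration
#'
#' Builds the initial tissue (healthy cubic blocks tiling the periodic box,
#' with a central sphere of cancer cells of the seed phenotype partitioned
#' into approximately `target_volume`-sized Voronoi pieces) and loads it into
#' the compiled lattice engine.
#'
#' The engine owns the lattice state; the returned object is a handle.  All
#' engine randomness comes from `config$rng_seed` (the initialization also
#' seeds R's RNG from it), so a run is reproducible from its configuration
#' alone.
#'
#' @param config A [run_config()].
#' @return An object of class `"cpm_sim"`.
#' @export
initialize_tissue <- function(config) {
  validate_run_config(config)
  L <- config$grid_side
  b <- config$healthy_block
  nb <- L %/% b
  set.seed(config$rng_seed)

  ax <- 0:(L - 1)
  bx <- ax %/% b
  # block id per voxel (column-major over x, y, z like the spin array)
  bid <- 1L + outer(outer(bx, nb * bx, `+`), nb * nb * bx, `+`)
  spins <- as.integer(bid)
  n_healthy <- nb^3

  ctr <- (L - 1) / 2
  X <- rep(ax, times = L * L)
  Y <- rep(rep(ax, each = L), times = L)
  Z <- rep(ax, each = L * L)
  d2 <- (X - ctr)^2 + (Y - ctr)^2 + (Z - ctr)^2
  in_sphere <- d2 <= config$seed_radius^2
  n_vox <- sum(in_sphere)
  if (n_vox < 1) stop("seed sphere contains no voxels", call. = FALSE)
  K <- max(1L, as.integer(round(n_vox / config$target_volume)))

  idx <- which(in_sphere)
  seeds <- sample(idx, K)
  # nearest-seed (Voronoi) partition of the sphere into K cancer cells
  best <- rep.int(1L, n_vox)
  bestd <- rep.int(Inf, n_vox)
  for (k in seq_len(K)) {
    dk <- (X[idx] - X[seeds[k]])^2 + (Y[idx] - Y[seeds[k]])^2 +
      (Z[idx] - Z[seeds[k]])^2
    upd <- dk < bestd
    best[upd] <- k
    bestd[upd] <- dk[upd]
  }
  spins[idx] <- n_healthy + best

  M <- n_healthy + K
  type <- c(rep.int(0L, n_healthy), rep.int(1L, K))
  ph <- initial_phenotype(config$initial_adhesion, config$initial_motility)
  pi_ <- c(rep.int(-1L, n_healthy), rep.int(ph$adh_index, K))
  pj_ <- c(rep.int(-1L, n_healthy), rep.int(ph$mot_index, K))
  birth <- rep.int(0, M)

  ptr <- cpp_sim_new(engine_params(config))
  cpp_sim_load(ptr, spins, type, pi_, pj_, birth)
  structure(list(ptr = ptr, config = config), class = "cpm_sim")
}

# parameter list consumed by the compiled engine
engine_params <- function(config) {
  config[c("grid_side", "target_volume", "volume_coupling", "target_surface",
           "surface_coupling", "temperature", "central_coupling",
           "motility_recalc_interval", "adhesion_healthy", "healthy_motility",
           "neighborhood", "division_age_min", "death_age_min",
           "division_volume_fraction", "max_division_rate", "max_death_rate",
           "mutation_probability", "mutation_boundary", "dependency_mode",
           "nutrient_mode", "orbit_amplitude", "orbit_period", "decay_radius",
           "rng_seed")]
}

#' Build a simulation from an explicit spin array
#'
#' Low-level constructor for tests and toy configurations: every voxel of
#' `spins` must carry a cell id in `1..max(spins)`, and per-cell bookkeeping
#' (volume, surface, center of mass) is computed from scratch.
#'
#' @param config A [run_config()] (its `grid_side` must match `dim(spins)`).
#' @param spins Integer L x L x L array of cell ids.
#' @param type Integer vector per cell: 0 healthy, 1 cancer.
#' @param adh_index,mot_index Phenotype grid indices per cell (0..11 for
#'   cancer, -1 for healthy).
#' @param birth_time Birth time per cell in MCS (default 0).
#' @return A `"cpm_sim"` object.
#' @export
sim_from_spins <- function(config, spins, type, adh_index, mot_index,
                           birth_time = rep(0, length(type))) {
  stopifnot(inherits(config, "run_config"),
            all(dim(spins) == rep(config$grid_side, 3)))
  M <- length(type)
  stopifnot(length(adh_index) == M, length(mot_index) == M,
            length(birth_time) == M,
            all(spins >= 1), all(spins <= M))
  ptr <- cpp_sim_new(engine_params(config))
  cpp_sim_load(ptr, as.integer(spins), as.integer(type),
               as.integer(adh_index), as.integer(mot_index),
               as.numeric(birth_time))
  structure(list(ptr = ptr, config = config), class = "cpm_sim")
}

#' @export
print.cpm_sim <- function(x, ...) {
  i <- cpp_sim_info(x$ptr)
  cat(sprintf("<cpm_sim: L=%d, t=%g MCS, %d cells (%g cancer)%s>\n",
              i$grid_side, i$time, i$n_cells, i$n_cancer,
              if (i$extinct) ", extinct" else ""))
  invisible(x)
}

#' Export the lattice state
#'
#' @param sim A `"cpm_sim"`.
#' @return A list with `spins` (L x L x L integer array of cell ids, 0-based
#'   voxel coordinates run 0..L-1 along each dimension index), `cells` (data
#'   frame of per-cell bookkeeping: type, phenotype indices, volume, surface,
#'   center of mass in unwrapped voxel coordinates, birth time, motility
#'   direction, targets, alive/dying flags), and `time`.
#' @export
sim_state <- function(sim) {
  stopifnot(inherits(sim, "cpm_sim"))
  cpp_sim_state(sim$ptr)
}

#' Engine counters and status
#'
#' @param sim A `"cpm_sim"`.
#' @return List with grid side, current time, attempt/accept/no-op counters,
#'   live cancer-cell count, total cell-id count, and extinction flag.
#' @export
sim_info <- function(sim) cpp_sim_info(sim$ptr)

#' Verify incremental bookkeeping against a brute-force rebuild
#'
#' Recomputes every cell's volume, surface, and center of mass directly from
#' the spin array and reports the largest discrepancy against the
#' incrementally maintained caches, plus the total volume (which must equal
#' L^3: the lattice is a tessellation).
#'
#' @param sim A `"cpm_sim"`.
#' @return List with `max_volume_diff`, `max_surface_diff`, `max_com_diff`,
#'   `sum_volume`.
#' @export
sim_check_consistency <- function(sim) cpp_sim_check(sim$ptr)

#' Fragment audit
#'
#' No connectivity constraint is enforced in the dynamics; this counts, for
#' every live cell, its connected components under the flip neighborhood so
#' fragmentation can be monitored.
#'
#' @param sim A `"cpm_sim"`.
#' @return Data frame with `cell_id` and `components`.
#' @export
sim_fragments <- function(sim) cpp_sim_fragments(sim$ptr)

#' Run Monte Carlo sweeps
#'
#' One sweep performs L^3 spin-flip attempts at uniformly random sites, each
#' proposing to copy the spin of a uniformly random lattice neighbor, accepted
#' by the Metropolis criterion at temperature `temperature`.  Bookkeeping is
#' updated incrementally.  Sweeps alone do not advance the lifecycle clock;
#' use [advance_simulation()] for full simulation steps.
#'
#' @param sim A `"cpm_sim"`.
#' @param n Number of sweeps.
#' @return Counters for this call: attempts, accepts, no-ops.
#' @export
monte_carlo_sweep <- function(sim, n = 1) {
  stopifnot(inherits(sim, "cpm_sim"), n >= 0)
  if (n == 0) return(list(attempts = 0, accepts = 0, noops = 0))
  cpp_sim_sweep(sim$ptr, as.integer(n))
}

#' Incremental energy change of a single flip attempt
#'
#' Returns `H(after) - H(before)` for copying `candidate_id` onto `site`,
#' computed incrementally from local volume, surface, adhesion, motility, and
#' central-potential deltas.  The candidate must be the current occupant of
#' the site (a no-op: 0) or of one of its lattice neighbors.
#'
#' @param sim A `"cpm_sim"`.
#' @param site Integer 3-vector (x, y, z), 1-based lattice indices.
#' @param candidate_id Cell id to copy in.
#' @return The energy change (scalar).
#' @export
delta_hamiltonian <- function(sim, site, candidate_id) {
  cpp_sim_delta_h(sim$ptr, as.integer(site), as.integer(candidate_id))
}

#' Apply a flip unconditionally
#'
#' Applies the spin copy regardless of its energy change (no Metropolis
#' draw) and updates all bookkeeping; used to probe the energy landscape.
#'
#' @inheritParams delta_hamiltonian
#' @return The energy change of the applied flip.
#' @export
apply_flip <- function(sim, site, candidate_id) {
  cpp_sim_apply_flip(sim$ptr, as.integer(site), as.integer(candidate_id))
}

#' Metropolis acceptance rule
#'
#' Accepts a proposed change with probability `min(1, exp(-delta_h /
#' temperature))`.  Vectorized over `delta_h`; uses R's RNG.
#'
#' @param delta_h Energy change(s) of the proposed flip(s).
#' @param temperature Metropolis temperature (> 0).
#' @return Logical vector of acceptances.
#' @export
metropolis_accept <- function(delta_h, temperature) {
  stopifnot(temperature > 0)
  runif(length(delta_h)) < pmin(1, exp(-delta_h / temperature))
}

#' Redraw every cell's motility direction
#'
#' Each live cell's preferred direction is replaced by an independent uniform
#' random unit vector (engine RNG).  The run loop calls this every
#' `motility_recalc_interval` MCS.
#'
#' @param sim A `"cpm_sim"`.
#' @return `sim`, invisibly.
#' @export
reassign_motility_directions <- function(sim) {
  cpp_sim_reassign_motility(sim$ptr)
  invisible(sim)
}

#' Sample uniform unit direction vectors from the engine RNG
#'
#' @param sim A `"cpm_sim"`.
#' @param n Number of directions.
#' @return An n x 3 matrix of unit vectors.
#' @export
sample_unit_directions <- function(sim, n) cpp_sample_directions(sim$ptr, n)

#' Total Hamiltonian by brute-force voxel enumeration
#'
#' Recomputes every energy term directly from the exported spin array:
#' volume and surface elasticity, adhesion as the negative bond strength
#' summed over unlike-cell contact faces (each unordered face once; shared
#' area between adhering cells lowers the energy), the motility potential
#' `-m * (e . com)`, and the central potential `|lambda_c| * |com -
#' center|` on cancer cells.  This is the reference implementation used to validate the
#' incremental deltas of the engine; it is far too slow for the dynamics
#' loop.
#'
#' @param sim A `"cpm_sim"`.
#' @return List of per-term energies and their `total`.
#' @export
total_hamiltonian <- function(sim) {
  st <- sim_state(sim)
  cfg <- sim$config
  sp <- st$spins
  L <- dim(sp)[1]
  cells <- st$cells
  M <- nrow(cells)

  vol <- tabulate(as.vector(sp), nbins = M)
  if (any((vol > 0) != cells$alive))
    stop("cached alive flags inconsistent with the spin array", call. = FALSE)
  if (any(vol != cells$volume))
    stop("cached volumes inconsistent with the spin array", call. = FALSE)
  alive <- vol > 0

  E_vol <- sum(cfg$volume_coupling *
                 (vol[alive] - cells$target_volume[alive])^2)

  offs <- half_offsets(cfg$neighborhood)
  surface <- numeric(M)
  E_adh <- 0
  is_cancer <- cells$type == 1L
  for (k in seq_len(nrow(offs))) {
    sh <- shift_lattice(sp, offs[k, ])
    mask <- sp != sh
    a <- sp[mask]
    b <- sh[mask]
    surface <- surface + tabulate(a, nbins = M) + tabulate(b, nbins = M)
    J <- ifelse(is_cancer[a] & is_cancer[b],
                -5 * (cells$adh_index[a] + cells$adh_index[b]),
                -cfg$adhesion_healthy)
    E_adh <- E_adh + sum(J)
  }
  E_surf <- sum(cfg$surface_coupling *
                  (surface[alive] - cells$target_surface[alive])^2)

  # center of mass from scratch: image of each voxel nearest the cached COM
  ax <- 0:(L - 1)
  X <- rep(ax, times = L * L)
  Y <- rep(rep(ax, each = L), times = L)
  Z <- rep(ax, each = L * L)
  spv <- as.vector(sp)
  ix <- X + L * floor((cells$com_x[spv] - X) / L + 0.5)
  iy <- Y + L * floor((cells$com_y[spv] - Y) / L + 0.5)
  iz <- Z + L * floor((cells$com_z[spv] - Z) / L + 0.5)
  sums <- rowsum(cbind(ix, iy, iz), group = spv)
  ids <- as.integer(rownames(sums))
  com <- matrix(NA_real_, M, 3)
  com[ids, ] <- sums / vol[ids]

  m <- ifelse(is_cancer, 10 * cells$mot_index, cfg$healthy_motility)
  sel <- alive & m != 0
  E_mot <- -sum(m[sel] * (cells$dir_x[sel] * com[sel, 1] +
                            cells$dir_y[sel] * com[sel, 2] +
                            cells$dir_z[sel] * com[sel, 3]))

  ctr <- (L - 1) / 2
  selc <- alive & is_cancer
  E_cen <- sum(abs(cfg$central_coupling) *
                 sqrt((com[selc, 1] - ctr)^2 + (com[selc, 2] - ctr)^2 +
                        (com[selc, 3] - ctr)^2))

  list(total = E_vol + E_surf + E_adh + E_mot + E_cen,
       volume = E_vol, surface = E_surf, adhesion = E_adh,
       motility = E_mot, central = E_cen)
}

# offsets counting each unordered neighbor pair once
half_offsets <- function(neighborhood) {
  if (neighborhood == 6) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else {
    o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    keep <- o[, 1] > 0 | (o[, 1] == 0 & o[, 2] > 0) |
      (o[, 1] == 0 & o[, 2] == 0 & o[, 3] > 0)
    unname(o[keep, , drop = FALSE])
  }
}

# periodic shift: result[x,y,z] = a[x+d1, y+d2, z+d3] (wrapped)
shift_lattice <- function(a, d) {
  L <- dim(a)[1]
  ix <- ((seq_len(L) - 1 + d[1]) %% L) + 1
  iy <- ((seq_len(L) - 1 + d[2]) %% L) + 1
  iz <- ((seq_len(L) - 1 + d[3]) %% L) + 1
  a[ix, iy, iz, drop = FALSE]
}
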