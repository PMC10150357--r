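# Shared builders for small lattice states used across the test files.

# block tiling of an L-box into cubic cells of side b (spin array + ids)
block_tiling <- function(L, b) {
  ax <- 0:(L - 1)
  bx <- ax %/% b
  nb <- L %/% b
  array(1L + outer(outer(bx, nb * bx, `+`), nb * nb * bx, `+`),
        dim = c(L, L, L))
}

# small tissue with randomized cancer phenotypes and a few mixing sweeps;
# exercises every Hamiltonian term (healthy motility included)
random_test_sim <- function(seed = 1, L = 16, sweeps = 15,
                            neighborhood = 6, healthy_motility = 20) {
  cfg <- run_config(grid_side = L, seed_radius = 5, healthy_block = 8,
                    relax_mcs = 0, run_length = 0, rng_seed = seed,
                    neighborhood = neighborhood,
                    healthy_motility = healthy_motility)
  sim <- initialize_tissue(cfg)
  st <- sim_state(sim)
  cancer_ids <- st$cells$cell_id[st$cells$type == 1L]
  set.seed(seed)
  for (id in cancer_ids) {
    sim_set_phenotype(sim, id, sample(0:11, 1), sample(0:11, 1))
  }
  if (sweeps > 0) monte_carlo_sweep(sim, sweeps)
  sim
}

# two adjacent 8^3 cancer blocks (ids 1, 2) inside a 16^3 healthy tiling
two_cancer_block_sim <- function(seed = 1, adh_index = 0, mot_index = 0,
                                 ...) {
  L <- 16
  cfg <- run_config(grid_side = L, seed_radius = 5, healthy_block = 8,
                    relax_mcs = 0, run_length = 0, rng_seed = seed, ...)
  spins <- block_tiling(L, 8)
  M <- max(spins)
  type <- integer(M)
  type[1:2] <- 1L
  pi_ <- rep(-1L, M); pj_ <- rep(-1L, M)
  pi_[1:2] <- adh_index; pj_[1:2] <- mot_index
  sim_from_spins(cfg, spins, type, pi_, pj_)
}

# contact faces between two cell ids (6-neighborhood), periodic
shared_faces <- function(spins, id_a, id_b) {
  total <- 0
  for (d in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    L <- dim(spins)[1]
    ix <- ((seq_len(L) - 1 + d[1]) %% L) + 1
    iy <- ((seq_len(L) - 1 + d[2]) %% L) + 1
    iz <- ((seq_len(L) - 1 + d[3]) %% L) + 1
    sh <- spins[ix, iy, iz]
    total <- total + sum(spins == id_a & sh == id_b) +
      sum(spins == id_b & sh == id_a)
  }
  total
}

# The reduced-scale study profile used by the qualitative spheroid checks:
# replicated desk runs, computed once and cached for the whole test session.
desk_profile_runs <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    runs <- lapply(1:10, function(r) {
      cfg <- run_config(grid_side = 48, seed_radius = 16, run_length = 14000,
                        composition_cadence = 200,
                        rng_seed = derive_seed(2024, 0, r))
      out <- run_simulation(cfg)
      list(composition = out$composition, events = out$events,
           status = out$status)
    })
    cache <<- runs
    runs
  }
})
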