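test_that("hand-computed energies match the brute-force Hamiltonian", {
  # a 9 x 10 x 5 box (450 voxels) of one healthy cell inside another
  L <- 16
  cfg <- run_config(grid_side = L, seed_radius = 5, healthy_block = 8,
                    relax_mcs = 0, run_length = 0, rng_seed = 1,
                    healthy_motility = 0)
  spins <- array(1L, dim = c(L, L, L))
  spins[1:9, 1:10, 1:5] <- 2L
  sim <- sim_from_spins(cfg, spins, type = c(0L, 0L), adh_index = c(-1L, -1L),
                        mot_index = c(-1L, -1L))
  H <- total_hamiltonian(sim)
  box_faces <- 2 * (9 * 10 + 10 * 5 + 9 * 5)  # 370
  expect_equal(H$volume, 8 * ((450 - 500)^2 + (L^3 - 450 - 500)^2))
  expect_equal(H$surface, 6 * 2 * (box_faces - 400)^2)
  expect_equal(H$adhesion, -50 * box_faces)  # shared area lowers the energy
  expect_equal(H$motility, 0)
  expect_equal(H$central, 0)                 # no cancer cells
  # single-cell volume-term example: lambda_V (450 - 500)^2 = 20000
  expect_equal(8 * (450 - 500)^2, 20000)
})

test_that("incremental delta-H equals the brute-force energy difference", {
  # chained random flips on randomized small states, 6- and 26-neighborhood
  cases <- list(list(seed = 1, nb = 6, n = 400), list(seed = 2, nb = 6, n = 400),
                list(seed = 3, nb = 26, n = 250))
  for (cs in cases) {
    sim <- random_test_sim(seed = cs$seed, neighborhood = cs$nb)
    offs <- if (cs$nb == 6) {
      rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
            c(0, 0, 1), c(0, 0, -1))
    } else {
      o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
      o[rowSums(abs(o)) > 0, ]
    }
    set.seed(100 + cs$seed)
    h_before <- total_hamiltonian(sim)$total
    for (k in seq_len(cs$n)) {
      site <- sample(16, 3, replace = TRUE)
      nb <- ((site - 1 + offs[sample(nrow(offs), 1), ]) %% 16) + 1
      st <- sim_state(sim)
      cand <- st$spins[nb[1], nb[2], nb[3]]
      dh <- apply_flip(sim, site, cand)
      h_after <- total_hamiltonian(sim)$total
      expect_lt(abs((h_after - h_before) - dh) / max(1, abs(dh)), 1e-9)
      h_before <- h_after
    }
    chk <- sim_check_consistency(sim)
    expect_equal(chk$max_volume_diff, 0)
    expect_equal(chk$max_surface_diff, 0)
    expect_lt(chk$max_com_diff, 1e-9)
    expect_equal(chk$sum_volume, 16^3)
  }
})

test_that("a no-op attempt has zero energy change", {
  sim <- random_test_sim(seed = 4)
  st <- sim_state(sim)
  expect_identical(delta_hamiltonian(sim, c(3, 3, 3), st$spins[3, 3, 3]), 0)
  # candidates outside the neighborhood are rejected
  far_id <- st$spins[14, 14, 14]
  if (far_id != st$spins[3, 3, 3]) {
    expect_error(delta_hamiltonian(sim, c(3, 3, 3), far_id), "neighborhood")
  }
})

test_that("moving a cancer cell toward the central potential lowers the energy", {
  # one cancer block, all couplings but the central potential switched off
  L <- 16
  cfg <- run_config(grid_side = L, seed_radius = 5, healthy_block = 8,
                    relax_mcs = 0, run_length = 0, rng_seed = 2,
                    volume_coupling = 0, surface_coupling = 0,
                    adhesion_healthy = 0, central_coupling = -70)
  spins <- array(1L, dim = c(L, L, L))
  spins[3:7, 7:10, 7:10] <- 2L          # cancer box left of center
  sim <- sim_from_spins(cfg, spins, type = c(0L, 1L), adh_index = c(-1L, 0L),
                        mot_index = c(-1L, 0L))
  sim_set_direction(sim, 2, c(1, 0, 0))  # motility strength is 0 anyway
  st <- sim_state(sim)
  com <- c(st$cells$com_x[2], st$cells$com_y[2], st$cells$com_z[2])
  ctr <- rep((L - 1) / 2, 3)
  # grow the box by one voxel on its center-facing side
  site <- c(8, 8, 8)
  v <- st$cells$volume[2]
  new_com <- (com * v + (site - 1)) / (v + 1)
  delta_dist <- sqrt(sum((new_com - ctr)^2)) - sqrt(sum((com - ctr)^2))
  expect_lt(delta_dist, 0)
  dh <- delta_hamiltonian(sim, site, 2)
  expect_equal(dh, 70 * delta_dist, tolerance = 1e-9)
})

test_that("Metropolis acceptance matches the closed form", {
  # always accept non-positive energy changes
  set.seed(8)
  expect_true(all(metropolis_accept(rep(0, 1000), 55)))
  expect_true(all(metropolis_accept(rep(-10, 1000), 55)))
  n <- 1e5
  for (dh in c(27.5, 55, 110)) {
    p <- exp(-dh / 55)
    acc <- mean(metropolis_accept(rep(dh, n), 55))
    expect_lt(abs(acc - p), 3 * sqrt(p * (1 - p) / n))
  }
  expect_error(metropolis_accept(1, 0))
})

test_that("sweeps preserve the tessellation and the bookkeeping caches", {
  sim <- random_test_sim(seed = 6, sweeps = 0)
  for (k in 1:5) {
    monte_carlo_sweep(sim, 4)
    chk <- sim_check_consistency(sim)
    expect_equal(chk$sum_volume, 16^3)
    expect_equal(chk$max_volume_diff, 0)
    expect_equal(chk$max_surface_diff, 0)
    expect_lt(chk$max_com_diff, 1e-9)
  }
  # independent R-side rebuild of volumes from the exported spins
  st <- sim_state(sim)
  expect_equal(tabulate(as.vector(st$spins), nbins = nrow(st$cells)),
               st$cells$volume)
})

test_that("a homogeneous lattice never changes", {
  L <- 8
  cfg <- run_config(grid_side = L, seed_radius = 3, healthy_block = 8,
                    relax_mcs = 0, run_length = 0, rng_seed = 1)
  spins <- array(1L, dim = c(L, L, L))
  sim <- sim_from_spins(cfg, spins, type = 0L, adh_index = -1L,
                        mot_index = -1L)
  ct <- monte_carlo_sweep(sim, 3)
  expect_equal(ct$noops, ct$attempts)
  expect_true(all(sim_state(sim)$spins == 1L))
})

test_that("with all couplings zero the two-cell toy shows no volume drift", {
  wins <- 0
  reps <- 24
  for (r in seq_len(reps)) {
    L <- 8
    cfg <- run_config(grid_side = L, seed_radius = 3, healthy_block = 8,
                      relax_mcs = 0, run_length = 0, rng_seed = 1000 + r,
                      volume_coupling = 0, surface_coupling = 0,
                      adhesion_healthy = 0, central_coupling = 0)
    spins <- array(1L, dim = c(L, L, L))
    spins[, , 5:8] <- 2L
    sim <- sim_from_spins(cfg, spins, type = c(0L, 0L),
                          adh_index = c(-1L, -1L), mot_index = c(-1L, -1L))
    monte_carlo_sweep(sim, 30)
    v1 <- sim_state(sim)$cells$volume[1]
    if (v1 > L^3 / 2) wins <- wins + 1
    if (v1 == L^3 / 2) wins <- wins + 0.5
  }
  # symmetric occupancy: neither cell systematically outgrows the other
  expect_gte(wins, 4)
  expect_lte(wins, 20)
})

test_that("weakly adhering cancer pairs lose shared boundary to the tissue", {
  # cancer-cancer bond strength 0 vs healthy reference 50: interposing
  # healthy tissue lowers the energy, so the shared interface should shrink
  diffs <- vapply(1:10, function(r) {
    sim <- two_cancer_block_sim(seed = 300 + r, adh_index = 0, mot_index = 0)
    before <- shared_faces(sim_state(sim)$spins, 1, 2)
    monte_carlo_sweep(sim, 100)
    after <- shared_faces(sim_state(sim)$spins, 1, 2)
    after - before
  }, numeric(1))
  expect_lt(mean(diffs), 0)
  expect_gte(sum(diffs < 0), 8)
})

test_that("motility directions are unit vectors, isotropic, and reproducible", {
  sim <- random_test_sim(seed = 12, sweeps = 0)
  reassign_motility_directions(sim)
  st <- sim_state(sim)
  live <- st$cells[st$cells$alive, ]
  norms <- sqrt(live$dir_x^2 + live$dir_y^2 + live$dir_z^2)
  expect_true(all(abs(norms - 1) < 1e-12))

  dirs <- sample_unit_directions(sim, 1e5)
  expect_true(all(abs(sqrt(rowSums(dirs^2)) - 1) < 1e-12))
  # each component has mean 0 and variance 1/3
  se <- sqrt(1 / 3 / nrow(dirs))
  expect_true(all(abs(colMeans(dirs)) < 3 * se))

  sim2 <- random_test_sim(seed = 12, sweeps = 0)
  reassign_motility_directions(sim2)
  st2 <- sim_state(sim2)
  expect_identical(st$cells$dir_x, st2$cells$dir_x)
})
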