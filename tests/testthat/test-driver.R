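test_that("tissue initialization tiles the box and seeds the tumor", {
  cfg <- run_config(grid_side = 32, seed_radius = 12, relax_mcs = 0,
                    run_length = 0, rng_seed = 5)
  sim <- initialize_tissue(cfg)
  chk <- sim_check_consistency(sim)
  expect_equal(chk$sum_volume, 32^3)
  expect_equal(chk$max_volume_diff, 0)
  st <- sim_state(sim)
  cancer <- st$cells[st$cells$type == 1L & st$cells$alive, ]
  # all seed cells carry the configured initial phenotype
  expect_true(all(cancer$adh_index == 5L & cancer$mot_index == 5L))
  # healthy cells carry no phenotype
  expect_true(all(st$cells$adh_index[st$cells$type == 0L] == -1L))
  # cell count matches the geometric packing estimate within 20%
  expected <- 4 / 3 * pi * 12^3 / 500
  expect_lt(abs(nrow(cancer) - expected) / expected, 0.2)
  # total cancer volume equals the voxelized sphere
  ax <- 0:31
  d2 <- outer(outer((ax - 15.5)^2, (ax - 15.5)^2, `+`), (ax - 15.5)^2, `+`)
  expect_equal(sum(cancer$volume), sum(d2 <= 144))
})

test_that("oversized seeds and bad configurations are rejected", {
  expect_error(run_config(grid_side = 32, seed_radius = 16), "seed_radius")
  expect_error(run_config(grid_side = 30, healthy_block = 8), "divide")
  expect_error(run_config(initial_adhesion = 55), "discrete grid")
  expect_error(run_config(max_division_rate = 2), "rates")
  expect_error(run_config(nutrient_mode = "orbiting", orbit_period = 0),
               "orbit_period")
})

test_that("a zero-length run returns the initialization state", {
  cfg <- run_config(grid_side = 16, seed_radius = 5, relax_mcs = 0,
                    run_length = 0, rng_seed = 2)
  res <- run_simulation(cfg)
  expect_equal(res$status, "completed")
  expect_equal(nrow(res$events), 0)
  expect_equal(unique(res$composition$time_mcs), 0)
  # composition row sums equal the live cancer-cell count
  st <- sim_state(res$sim)
  expect_equal(sum(res$composition$count),
               sum(st$cells$type == 1L & st$cells$alive & !st$cells$dying))
})

test_that("identical configurations reproduce byte-identical outputs", {
  cfg <- run_config(grid_side = 16, seed_radius = 5, run_length = 300,
                    composition_cadence = 100, relax_mcs = 10, rng_seed = 31,
                    division_age_min = 0, death_age_min = 100)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_simulation(cfg, out_dir = d1)
  run_simulation(cfg, out_dir = d2)
  for (f in c("composition.tsv", "events.tsv", "centroids.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  cfg2 <- cfg
  cfg2$rng_seed <- 32L
  r1 <- run_simulation(cfg)
  r3 <- run_simulation(cfg2)
  expect_false(identical(sim_state(r1$sim)$spins, sim_state(r3$sim)$spins))
})

test_that("composition samples track the live cancer population", {
  cfg <- run_config(grid_side = 16, seed_radius = 5, run_length = 400,
                    composition_cadence = 100, relax_mcs = 0, rng_seed = 8)
  res <- run_simulation(cfg)
  tot <- rowsum(res$composition$count, res$composition$time_mcs)
  expect_equal(as.numeric(rownames(tot)), seq(0, 400, by = 100))
  expect_true(all(tot >= 0))
  st <- sim_state(res$sim)
  expect_equal(unname(tot[nrow(tot), 1]),
               sum(st$cells$type == 1L & st$cells$alive & !st$cells$dying))
})

test_that("loss of the cancer population terminates the run gracefully", {
  # immediate universal death: the tumor shrinks away and the run stops
  # early with the extinction recorded
  cfg <- run_config(grid_side = 16, seed_radius = 5, run_length = 2000,
                    composition_cadence = 50, relax_mcs = 0, rng_seed = 13,
                    dependency_mode = "none", death_age_min = 0,
                    max_death_rate = 1, max_division_rate = 0)
  res <- run_simulation(cfg)
  expect_equal(res$status, "extinct")
  info <- sim_info(res$sim)
  expect_true(info$extinct)
  expect_equal(info$n_cancer, 0)
  expect_lt(info$time, 2000)
  # final composition sample is empty; the tessellation survives
  tot <- rowsum(res$composition$count, res$composition$time_mcs)
  expect_equal(unname(tot[nrow(tot), 1]), 0)
  expect_equal(sim_check_consistency(res$sim)$sum_volume, 16^3)
})

test_that("period sweeps run all conditions with derived seeds", {
  cfg <- run_config(grid_side = 16, seed_radius = 5, run_length = 400,
                    composition_cadence = 100, relax_mcs = 0, rng_seed = 99)
  summ <- sweep_periods(cfg, periods = c(200, 400), replicates = 2,
                        speed_window = 200)
  expect_equal(nrow(summ), 6)  # 2 periods x 2 replicates + 2 controls
  expect_equal(sum(summ$period_mcs == 0), 2)
  expect_setequal(
    c("period_mcs", "replicate", "rng_seed", "status", "mean_speed",
      "mean_spread", "n_samples"), names(summ))
  expect_equal(summ$rng_seed,
               mapply(derive_seed, 99, summ$period_mcs, summ$replicate))
  # derivation is deterministic and collision-free here
  expect_equal(length(unique(summ$rng_seed)), 6)
  summ2 <- sweep_periods(cfg, periods = c(200, 400), replicates = 2,
                         speed_window = 200)
  expect_equal(summ, summ2)
})

test_that("run configurations round-trip through YAML", {
  cfg <- run_config(grid_side = 48, seed_radius = 10, nutrient_mode = "orbiting",
                    orbit_period = 5000, rng_seed = 12)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  cfg2 <- read_run_config(f)
  expect_equal(cfg2, cfg)
  writeLines(c("grid_side: 16", "not_a_key: 3"), f)
  expect_error(read_run_config(f), "unknown configuration keys")
})

test_that("VTK snapshots carry the full lattice", {
  cfg <- run_config(grid_side = 16, seed_radius = 5, relax_mcs = 0,
                    run_length = 0, rng_seed = 3)
  sim <- initialize_tissue(cfg)
  f <- withr::local_tempfile(fileext = ".vtk")
  write_snapshot_vtk(sim, f)
  lines <- readLines(f)
  expect_equal(lines[4], "DATASET STRUCTURED_POINTS")
  expect_equal(lines[5], "DIMENSIONS 16 16 16")
  vals <- as.integer(lines[-(1:10)])
  expect_equal(length(vals), 16^3)
  expect_equal(vals, as.vector(sim_state(sim)$spins))
  # availability field: one bounded float per voxel
  write_snapshot_vtk(sim, f, field = "nutrient")
  lines <- readLines(f)
  expect_equal(lines[9], "SCALARS nutrient float 1")
  nv <- as.numeric(lines[-(1:10)])
  expect_equal(length(nv), 16^3)
  expect_true(all(nv >= 0 & nv <= 1))
})

test_that("the command-line interface drives run and sweep", {
  cfg <- run_config(grid_side = 16, seed_radius = 5, run_length = 200,
                    composition_cadence = 100, relax_mcs = 0, rng_seed = 1)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, f)
  out <- withr::local_tempdir()
  expect_message(
    status <- spheroidevo_cli(c("run", "--config", f, "--seed", "7",
                                "--out", out)),
    "run completed")
  expect_equal(status, 0L)
  expect_true(file.exists(file.path(out, "composition.tsv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$config$rng_seed, 7)
  expect_error(spheroidevo_cli(c("run", "--config")), "needs a value")
  expect_equal(suppressMessages(spheroidevo_cli(character(0))), 1L)
})
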