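test_that("excitation injects exactly the (3/2) n kB dT kinetic energy", {
  s <- small_channel()
  n <- n_atoms(s)
  masses <- rep(110, n)
  set.seed(1)
  dirn <- rnorm(3 * n)
  v0 <- maxwell_velocities(masses, 300)
  for (dT in c(4, 0.5)) {
    dv <- excite(rep(0, 3 * n), masses, dirn, dT) # from rest: the increment
    e <- kinetic_energy(dv, masses)
    target <- 1.5 * n * 0.001987204259 * dT
    expect_lt(abs(e / target - 1), 1e-9)
    ## additivity: the same increment on thermal velocities
    v1 <- excite(v0, masses, dirn, dT)
    expect_equal(v1 - v0, dv, tolerance = 1e-12)
  }
  expect_identical(excite(v0, masses, dirn, 0), v0)
  expect_error(excite(v0, masses, rep(0, 3 * n), 4), "zero")
  ## opposite directions cancel from rest
  v <- excite(rep(0, 3 * n), masses, dirn, 4)
  v <- excite(v, masses, -dirn, 4)
  expect_lt(max(abs(v)), 1e-12)
})

test_that("one selected mode yields the two antipodal directions", {
  s <- blob_structure(10)
  m <- compute_modes(build_hessian(s, cutoff = 10), n_modes = 8)
  m$selection <- data.frame(mode = 7, frequency = m$frequencies[7],
                            channel_score = 1, shape = "spherical",
                            selected = TRUE)
  expect_warning(dirs <- combine_modes(m, 3, seed = 1), "two distinct")
  expect_equal(ncol(dirs), 2L)
  expect_equal(dirs[, 1], -dirs[, 2], tolerance = 1e-12)
  expect_equal(sum(dirs[, 1]^2), 1, tolerance = 1e-12)
})

test_that("combined directions are unit, reproducible and well spaced", {
  s <- blob_structure(40)
  m <- compute_modes(build_hessian(s, cutoff = 12), n_modes = 10)
  m$selection <- data.frame(mode = 7:10, frequency = m$frequencies[7:10],
                            channel_score = 1, shape = "spherical",
                            selected = TRUE)
  d1 <- combine_modes(m, 62, probe_rmsd = 1, seed = 42)
  d2 <- combine_modes(m, 62, probe_rmsd = 1, seed = 42)
  expect_identical(unclass(d1), unclass(d2))
  expect_equal(ncol(d1), 62L)
  expect_equal(unname(colSums(d1^2)), rep(1, 62), tolerance = 1e-9)
  ## pairwise RMSD of 1 A-displaced structures respects the floor
  floorA <- attr(d1, "min_rmsd_spacing")
  n <- n_atoms(s)
  disp <- apply(d1, 2, function(v) as.numeric(coords(
    displace_along(s, v, 1))))
  pd <- as.matrix(dist(t(disp))) / sqrt(n)
  expect_true(all(pd[upper.tri(pd)] >= floorA - 1e-9))
  ## any direction displaces to exactly the probe RMSD
  dd <- displace_along(s, d1[, 5], 1)
  expect_equal(sqrt(mean(rowSums((coords(dd) - coords(s))^2))), 1,
               tolerance = 1e-6)
})

test_that("replica dynamics are deterministic and book-keep energy", {
  s <- small_channel()
  pot <- enm_potential(s, cutoff = 10)
  dirn <- breathing_direction(default_channel())  # wrong length
  expect_error(run_replica(s, pot, dirn[1:10], excitation_config()), "")
  d <- local({ set.seed(2); v <- rnorm(3 * n_atoms(s)); v / sqrt(sum(v^2)) })
  cfg <- excitation_config(n_excitations = 3, relaxation_time = 0.2,
                           record_stride = 20, seed = 7)
  r1 <- run_replica(s, pot, d, cfg, replica_id = 2)
  r2 <- run_replica(s, pot, d, cfg, replica_id = 2)
  expect_identical(r1$trajectory$xyz, r2$trajectory$xyz)
  expect_equal(length(r1$injected_energy), 3L)
  expect_equal(sum(r1$injected_energy),
               3 * 1.5 * n_atoms(s) * 0.001987204259 * 4,
               tolerance = 1e-12)
  ## delta_T = 0 must follow plain Langevin dynamics exactly (same seed)
  cfg0 <- excitation_config(n_excitations = 3, relaxation_time = 0.2,
                            record_stride = 20, seed = 7, delta_T = 0)
  r0 <- run_replica(s, pot, d, cfg0, replica_id = 2)
  ens0 <- relax(list(s), pot, duration = 3 * 0.2, keep_fraction = 1,
                config = excitation_config(seed = 7 + 2 - 1, timestep = cfg0$timestep,
                                           record_stride = 20))
  expect_equal(r0$trajectory$xyz, ens0$xyz, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("kept relaxation frames are the exact trajectory tail", {
  expect_identical(mdenm:::.kept_frames(100, 0.75), 26:100)
  expect_identical(mdenm:::.kept_frames(101, 0.75), 27:101)
  expect_identical(mdenm:::.kept_frames(7, 1.0), 1:7)
  expect_identical(mdenm:::.kept_frames(4, 0.5), 3:4)
})
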