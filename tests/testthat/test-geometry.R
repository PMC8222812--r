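spec <- channel_spec()

test_that("kink angle: straight, right-angle and generator round-trip", {
  ## collinear trace over 46..80
  line <- atoms_at(cbind(0, 0, 1.5 * (46:80)), resno = 46:80)
  expect_lt(kink_angle(line)[["A"]], 1e-6)
  ## bend of exactly 90 degrees at residue 56
  p <- rbind(cbind(0, 0, seq(-15, 0, by = 1.5)),
             cbind(seq(1.5, 36, by = 1.5), 0, 0))
  bent <- atoms_at(p, resno = 46:80)
  expect_equal(kink_angle(bent)[["A"]], 90, tolerance = 1e-6)
  ## generator round-trip at the default 13-degree kink
  k <- kink_angle(default_channel())
  expect_equal(unname(k), rep(13, 4), tolerance = 2)
  ## endpoint-vector mode agrees for exactly straight segments
  k2 <- kink_angle(default_channel(), method = "endpoints")
  expect_equal(unname(k2), rep(13, 4), tolerance = 2)
})

test_that("kink angle is invariant under rigid-body isometries", {
  s <- default_channel()
  R <- mdenm:::rotation_about(c(1, -2, 0.5), 73)
  s2 <- transform_structure(s, R, c(11, -4, 7))
  expect_equal(kink_angle(s2), kink_angle(s), tolerance = 1e-6)
})

test_that("ctd_rotation follows the four-point dihedral construction", {
  ## both CAs in the same axial half-plane: 0 degrees
  s0 <- atoms_at(rbind(c(5, 0, 10), c(7, 0, -10)), resno = c(108, 266))
  expect_equal(ctd_rotation(s0)[["A"]], 0, tolerance = 1e-9)
  ## outer residue rotated +90 about z
  s90 <- atoms_at(rbind(c(5, 0, 10), c(0, 7, -10)), resno = c(108, 266))
  expect_equal(abs(ctd_rotation(s90)[["A"]]), 90, tolerance = 1e-9)
  ## equivariance: rotating the CTD by theta shifts the dihedral by theta
  s <- default_channel()
  base <- ctd_rotation(s)
  for (theta in c(33, -50, 140)) {
    rot <- s
    ctd <- rot$atoms$resno >= 134
    xyz <- coords(rot)
    xyz[ctd, ] <- xyz[ctd, ] %*% t(mdenm:::rotation_about(c(0, 0, 1), theta))
    coords(rot) <- xyz
    expect_deg_equal(ctd_rotation(rot) - base, rep(theta, 4), tol = 1e-6)
  }
  ## a point on the axis has no defined azimuth
  bad <- atoms_at(rbind(c(0, 0, 10), c(7, 0, -10)), resno = c(108, 266))
  expect_error(ctd_rotation(bad), "axis")
})

test_that("ctd_rotation is invariant when the axis is carried along", {
  s <- default_channel()
  R <- mdenm:::rotation_about(c(2, 1, 1), -41)
  tr <- c(3, -8, 2)
  s2 <- transform_structure(s, R, tr)
  expect_deg_equal(ctd_rotation(s2, axis = as.numeric(R %*% c(0, 0, 1)),
                                origin = tr),
                   ctd_rotation(s), tol = 1e-6)
})

test_that("per_residue_rmsd implements the per-atom ensemble formula", {
  s <- default_channel()
  ens <- as_ensemble(rep(list(s), 5))
  r0 <- per_residue_rmsd(ens, reference = s)
  expect_true(all(r0$rmsd == 0))

  ## single atom oscillating +-a: RMSD = a
  at <- atoms_at(rbind(c(0, 0, 0)))
  frames <- list(at, at)
  coords(frames[[1]]) <- c(0.7, 0, 0)
  coords(frames[[2]]) <- c(-0.7, 0, 0)
  r1 <- per_residue_rmsd(as_ensemble(frames), reference = at)
  expect_equal(r1$rmsd, 0.7)

  ## brute-force oracle on a random ensemble
  p <- synthetic_params(n_frames = 10, seed = 44)
  ens <- make_ensemble(p, spec)
  ref <- ensemble_frame(ens, 1)
  got <- per_residue_rmsd(ens, reference = ref)
  topo <- ens$topology
  refx <- coords(ref)
  for (pick in c(1, 57, 400)) {
    ch <- got$chain[pick]; rn <- got$resno[pick]
    idx <- which(topo$chain == ch & topo$resno == rn)
    vals <- vapply(idx, function(i) {
      cols <- 3 * (i - 1) + 1:3
      sqrt(mean(rowSums(
        (ens$xyz[, cols, drop = FALSE] -
           matrix(refx[i, ], n_frames(ens), 3, byrow = TRUE))^2)))
    }, numeric(1))
    expect_equal(got$rmsd[pick], mean(vals), tolerance = 1e-12)
  }
  ## isometry invariance: transforming frames and reference together
  R <- mdenm:::rotation_about(c(0, 1, 3), 57)
  tr <- c(-2, 5, 1)
  xyz2 <- t(apply(ens$xyz, 1, function(row) {
    m <- matrix(row, ncol = 3, byrow = TRUE) %*% t(R)
    as.numeric(t(sweep(m, 2, tr, "+")))
  }))
  ens2 <- channel_ensemble(topo, xyz2)
  ref2 <- transform_structure(ref, R, tr)
  got2 <- per_residue_rmsd(ens2, reference = ref2)
  expect_equal(got2$rmsd, got$rmsd, tolerance = 1e-6)
})

test_that("pore profile finds the constriction and respects axial symmetry", {
  ## four radius-1 atoms at distance 5 in one slab
  ring <- atoms_at(rbind(c(5, 0, 0), c(0, 5, 0), c(-5, 0, 0), c(0, -5, 0)))
  pr <- pore_radius_profile(ring, z_grid = 0, atom_radii = 1, slab = 1)
  expect_equal(pr$radius, 4)
  ## empty slab reported missing
  pr2 <- pore_radius_profile(ring, z_grid = c(0, 50), atom_radii = 1)
  expect_true(is.na(pr2$radius[2]))

  ## the profile minimum sits at the closed constriction's z level
  s <- default_channel("PARTIAL_124_OPEN_132_CLOSED")  # 132 closed
  z132 <- s$atoms$z[s$atoms$resno == 132 & s$atoms$atom_name == "SC" &
                    s$atoms$chain == "A"]
  pr3 <- pore_radius_profile(s, z_grid = seq(-40, 40, by = 1), slab = 1)
  zmin <- pr3$z[which.min(pr3$radius)]
  expect_lt(abs(zmin - z132), 1)

  ## invariance under rotation about the pore axis
  s2 <- transform_structure(s, mdenm:::rotation_about(c(0, 0, 1), 37))
  pr4 <- pore_radius_profile(s2, z_grid = seq(-40, 40, by = 1), slab = 1)
  expect_equal(pr4$radius, pr3$radius, tolerance = 1e-9)
})

test_that("geometry_report aggregates per-chain statistics", {
  p <- synthetic_params(n_frames = 4, seed = 3)
  ens <- make_ensemble(p, spec)
  g <- geometry_report(ens)
  expect_equal(nrow(g$angles), 4 * 4 * 2)
  expect_true(all(c("mean", "median", "sd") %in% names(g$summary)))
  km <- g$summary$mean[g$summary$metric == "kink_deg"]
  expect_equal(km, rep(13, 4), tolerance = 2, ignore_attr = TRUE)
})

test_that("pore axis estimation recovers the symmetry axis of tilted inputs", {
  s <- default_channel()
  est <- estimate_pore_axis(s)
  expect_equal(est$axis, c(0, 0, 1), tolerance = 1e-6)
  R <- mdenm:::rotation_about(c(1, 4, 2), 63)
  tr <- c(7, -3, 12)
  s2 <- transform_structure(s, R, tr)
  est2 <- estimate_pore_axis(s2)
  want <- as.numeric(R %*% c(0, 0, 1))
  if (want[3] < 0) want <- -want
  expect_equal(est2$axis, want, tolerance = 1e-6)
  ## the estimated frame reproduces the untilted rotation dihedral
  expect_deg_equal(ctd_rotation(s2, axis = est2$axis, origin = est2$origin),
                   ctd_rotation(s), tol = 1e-4)
})
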