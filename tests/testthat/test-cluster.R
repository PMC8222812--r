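spec <- channel_spec()

test_that("identical frames collapse to one cluster led by frame 1", {
  s <- default_channel()
  ens <- as_ensemble(rep(list(s), 5))
  cl <- cluster_frames(ens)
  expect_equal(length(cl$representatives), 1L)
  expect_true(all(cl$assignments == 1L))
  expect_equal(cl$representatives[[1]], 1L)
})

test_that("well-separated gating states recover the generator labels", {
  p <- synthetic_params(n_frames = 40,
                        state_probs = c(FULLY_OPEN = 0.5,
                                        FULLY_CLOSED = 0.5), seed = 21)
  ens <- make_ensemble(p, spec)
  cl <- cluster_frames(ens, region = c(121, 133), threshold = 0.9)
  expect_equal(length(cl$representatives), 2L)
  ## cluster ids partition the frames exactly along the labels
  expect_equal(length(unique(paste(cl$assignments, ens$labels))), 2L)
})

test_that("representatives minimize RMSD to their cluster mean and stay apart", {
  p <- synthetic_params(n_frames = 50, seed = 13)
  ens <- make_ensemble(p, spec)
  cl <- cluster_frames(ens)
  topo <- ens$topology
  region <- which(topo$resno >= 121 & topo$resno <= 133)
  fit <- which(topo$atom_name == "CA")
  frame_xyz <- function(i) matrix(ens$xyz[i, ], ncol = 3, byrow = TRUE)
  reg_fitted <- function(i, leader) {
    f <- mdenm:::kabsch(frame_xyz(i)[fit, ], frame_xyz(leader)[fit, ])
    mdenm:::.apply_fit(frame_xyz(i), f)[region, ]
  }
  for (L in seq_along(cl$representatives)) {
    members <- which(cl$assignments == L)
    leader <- members[1]
    regs <- lapply(members, reg_fitted, leader = leader)
    avg <- Reduce(`+`, regs) / length(regs)
    d <- vapply(regs, function(x) sqrt(mean(rowSums((x - avg)^2))),
                numeric(1))
    expect_equal(members[which.min(d)], cl$representatives[L])
  }
  ## representatives pairwise channel RMSD above the threshold
  if (length(cl$representatives) > 1) {
    reps <- cl$representatives
    for (a in seq_along(reps)) for (b in seq_len(a - 1)) {
      ra <- reg_fitted(reps[a], reps[b])
      rb <- frame_xyz(reps[b])[region, ]
      expect_gt(sqrt(mean(rowSums((ra - rb)^2))), cl$threshold)
    }
  }
})

test_that("frame order changes assignments but not representative spacing", {
  p <- synthetic_params(n_frames = 30,
                        state_probs = c(FULLY_OPEN = 0.4, FULLY_CLOSED = 0.3,
                                        GATE129_CLOSED = 0.3), seed = 31)
  ens <- make_ensemble(p, spec)
  set.seed(1)
  perm <- sample(n_frames(ens))
  ens_p <- channel_ensemble(ens$topology, ens$xyz[perm, , drop = FALSE],
                            labels = ens$labels[perm])
  cl <- cluster_frames(ens)
  cl_p <- cluster_frames(ens_p)
  expect_equal(length(cl_p$representatives), length(cl$representatives))
  topo <- ens$topology
  region <- which(topo$resno >= 121 & topo$resno <= 133)
  fit <- which(topo$atom_name == "CA")
  for (cc in list(list(cl, ens), list(cl_p, ens_p))) {
    reps <- cc[[1]]$representatives
    xyz <- cc[[2]]$xyz
    fx <- function(i) matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    for (a in seq_along(reps)) for (b in seq_len(a - 1)) {
      f <- mdenm:::kabsch(fx(reps[a])[fit, ], fx(reps[b])[fit, ])
      ra <- mdenm:::.apply_fit(fx(reps[a]), f)[region, ]
      expect_gt(sqrt(mean(rowSums((ra - fx(reps[b])[region, ])^2))), 0.9)
    }
  }
})

test_that("kabsch superposition matches the bio3d least-squares fit", {
  set.seed(6)
  A <- matrix(rnorm(60), ncol = 3)
  R0 <- mdenm:::rotation_about(c(1, 2, 2), 35)
  B <- A %*% t(R0) + matrix(rnorm(60, sd = 0.05), ncol = 3)
  fit <- mdenm:::kabsch(A, B)
  flat <- function(m) as.numeric(t(m))
  fitted_bio3d <- matrix(bio3d::fit.xyz(fixed = flat(B), mobile = flat(A),
                                        fixed.inds = 1:60,
                                        mobile.inds = 1:60),
                         ncol = 3, byrow = TRUE)
  expect_equal(mdenm:::.apply_fit(A, fit), fitted_bio3d, tolerance = 1e-6,
               ignore_attr = TRUE)
  ## noiseless data recovers the planted rotation exactly
  fit0 <- mdenm:::kabsch(A, A %*% t(R0))
  expect_equal(fit0$rotation, t(R0), tolerance = 1e-9)
})

test_that("relaxation keeps the trajectory tail at the bath temperature", {
  s <- small_channel()
  pot <- enm_potential(s, cutoff = 10)
  cfg <- excitation_config(seed = 3, record_stride = 25)
  ens <- relax(list(s, s), pot, duration = 6, keep_fraction = 0.75,
               config = cfg)
  prov <- attr(ens, "provenance")
  ## 6 ps / (25 x 2 fs) = 120 recorded + initial = 121; keep the last 90
  expect_equal(nrow(prov), 2 * 90)
  expect_equal(unique(prov$frame), 32:121)
  temps <- attr(ens, "kinetic_temperature")
  expect_lt(abs(mean(temps) / 300 - 1), 0.05)
})
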