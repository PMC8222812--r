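test_that("two-atom Hessian is the analytic rank-1 stretching block", {
  s <- two_atom_structure(d = 3)
  H <- build_hessian(s, cutoff = 5, spring_k = 2)
  expect_equal(dim(H), c(6L, 6L))
  expect_identical(H, t(H))
  ## single spring along x: only the xx entries are populated
  expect_equal(qr(H)$rank, 1L)
  expect_equal(H[1, 1], 2)
  expect_equal(H[1, 4], -2)
  expect_equal(H[2, 2], 0)
})

test_that("Hessian satisfies the translational sum rule", {
  s <- blob_structure(25)
  H <- build_hessian(s, cutoff = 10)
  for (k in 1:3) {
    t3 <- rep(0, 3); t3[k] <- 1
    expect_lt(max(abs(H %*% rep(t3, 25))), 1e-10)
  }
})

test_that("disconnected networks trigger a component-count warning", {
  far <- atoms_at(rbind(c(0, 0, 0), c(1, 0, 0), c(100, 0, 0), c(101, 0, 0)),
                  resno = 1:4)
  expect_warning(build_hessian(far, cutoff = 5), "2 components")
})

test_that("mode computation: ascending order, orthonormality, residuals", {
  s <- blob_structure(25)
  H <- build_hessian(s, cutoff = 10)
  m <- compute_modes(H, n_modes = 30)
  expect_true(all(diff(m$values) >= -1e-12))
  expect_equal(sum(m$zero), 6L)
  G <- crossprod(m$vectors)
  expect_lt(max(abs(G - diag(30))), 1e-8)
  res <- vapply(seq_len(30), function(k)
    sqrt(sum((H %*% m$vectors[, k] - m$values[k] * m$vectors[, k])^2)),
    numeric(1))
  expect_lt(max(res), 1e-6)
  expect_error(compute_modes(H, n_modes = 76), "exceeds")
})

test_that("two equal masses on one spring oscillate at 2k/m", {
  s <- two_atom_structure(d = 3)
  k <- 1.7; m <- 12
  H <- build_hessian(s, cutoff = 5, spring_k = k, masses = m)
  modes <- compute_modes(H, n_modes = 6)
  expect_equal(max(modes$values), 2 * k / m, tolerance = 1e-12)
})

test_that("displace_along hits the target RMSD and is linear in sign", {
  s <- default_channel()
  set.seed(4)
  v <- rnorm(3 * n_atoms(s))
  d0 <- displace_along(s, v, 0)
  expect_equal(coords(d0), coords(s), ignore_attr = TRUE)
  dp <- displace_along(s, v, 2, +1)
  expect_equal(sqrt(mean(rowSums((coords(dp) - coords(s))^2))), 2,
               tolerance = 1e-6)
  dm <- displace_along(s, v, 2, -1)
  mid <- (coords(dp) + coords(dm)) / 2
  expect_equal(max(abs(mid - coords(s))), 0, tolerance = 1e-9)
  expect_error(displace_along(s, rep(0, 3 * n_atoms(s)), 2), "zero")
})

test_that("gating-mode selection scores, classifies and ranks planted modes", {
  s <- default_channel()
  spec <- channel_spec()
  pm <- planted_mode_set(s, spec)
  out <- select_gating_modes(pm, s, spec, n_keep_first = 2, n_final = 2)
  sel <- out$selection
  ## mode 1 is a rigid rotation about the pore axis: distances invariant,
  ## so it scores zero and drops out of the top-scoring set
  expect_lt(sel$channel_score[sel$mode == 1], 1e-6)
  expect_false(sel$selected[sel$mode == 1])
  ## the breathing mode (3) has the largest channel score and is spherical
  expect_equal(sel$mode[which.max(sel$channel_score)], 3L)
  expect_equal(sel$shape[sel$mode == 3], "spherical")
  ## the A,C-out / B,D-in mode is elliptical
  expect_equal(sel$shape[sel$mode == 2], "elliptical")
  expect_true(all(c(2, 3) %in% sel$mode[sel$selected]))
})

test_that("selection is invariant to mode sign", {
  s <- default_channel()
  spec <- channel_spec()
  pm <- planted_mode_set(s, spec)
  flipped <- pm
  flipped$vectors <- -flipped$vectors
  a <- select_gating_modes(pm, s, spec, n_keep_first = 4, n_final = 2)
  b <- select_gating_modes(flipped, s, spec, n_keep_first = 4, n_final = 2)
  expect_equal(a$selection$channel_score, b$selection$channel_score,
               tolerance = 1e-9)
  expect_identical(a$selection$shape, b$selection$shape)
  expect_identical(a$selection$selected, b$selection$selected)
})

test_that("mode sets survive a plain-text round trip", {
  s <- blob_structure(10)
  m <- compute_modes(build_hessian(s, cutoff = 10), n_modes = 8)
  prefix <- file.path(withr::local_tempdir(), "modes")
  write_mode_set(m, prefix)
  m2 <- read_mode_set(prefix)
  expect_equal(m2$values, m$values, tolerance = 1e-12)
  expect_equal(m2$vectors, m$vectors, tolerance = 1e-12)
  expect_equal(m2$zero, m$zero)
})
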