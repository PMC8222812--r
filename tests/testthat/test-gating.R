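spec <- channel_spec()

test_that("shortest_distance equals the brute-force all-pairs minimum", {
  ## hand cases
  s <- atoms_at(rbind(c(0, 0, 0), c(3, 4, 0)), resno = c(1, 2))
  expect_equal(shortest_distance(s, list(resno = 1, chain = "A"),
                                 list(resno = 2, chain = "A")), 5)
  s0 <- atoms_at(rbind(c(1, 1, 1), c(5, 5, 5), c(1, 1, 1)),
                 resno = c(1, 1, 2))
  expect_equal(shortest_distance(s0, list(resno = 1, chain = "A"),
                                 list(resno = 2, chain = "A")), 0)
  expect_error(shortest_distance(s0, list(resno = 1, chain = "A"),
                                 list(resno = 9, chain = "A")),
               "residue 9")
  ## randomized oracle: 100 instances, exact agreement
  set.seed(99)
  for (rep in 1:100) {
    na <- sample(1:20, 1); nb <- sample(1:20, 1)
    xa <- matrix(rnorm(3 * na, sd = 5), ncol = 3)
    xb <- matrix(rnorm(3 * nb, sd = 5), ncol = 3)
    s <- atoms_at(rbind(xa, xb), resno = rep(c(1, 2), c(na, nb)))
    brute <- min(apply(xa, 1, function(p)
      apply(xb, 1, function(q) sqrt(sum((p - q)^2)))))
    expect_equal(shortest_distance(s, list(resno = 1, chain = "A"),
                                   list(resno = 2, chain = "A")),
                 brute, tolerance = 1e-12)
  }
})

test_that("gate distances reflect the construction and its C4 symmetry", {
  open <- default_channel("FULLY_OPEN")
  d <- gate_distances(open, spec)
  expect_true(all(d > spec$ionic_diameter))
  g129 <- default_channel("GATE129_CLOSED")
  d129 <- gate_distances(g129, spec)
  expect_lt(min(d129[c("d129_AC", "d129_BD")]), spec$ionic_diameter)
  expect_true(all(d129[c("d124_AC", "d124_BD", "d132_AC", "d132_BD")] >
                  spec$ionic_diameter))
  ## C4 symmetry: the two diametric pairs agree at every level
  expect_equal(d[c(1, 3, 5)], d[c(2, 4, 6)], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("classify_state implements the five-state decision table", {
  mk <- function(d124, d132, d129) {
    d <- c(d124, d132, d129)
    names(d) <- c("d124_AC", "d124_BD", "d132_AC", "d132_BD",
                  "d129_AC", "d129_BD")
    d
  }
  expect_equal(as.character(classify_state(mk(c(5, 5), c(5, 5), c(5, 5)), spec)),
               "FULLY_OPEN")
  expect_equal(as.character(classify_state(mk(c(5, 5), c(5, 5), c(2, 5)), spec)),
               "GATE129_CLOSED")
  expect_equal(as.character(classify_state(mk(c(5, 5), c(2, 2), c(5, 5)), spec)),
               "PARTIAL_124_OPEN_132_CLOSED")
  expect_equal(as.character(classify_state(mk(c(2, 2), c(5, 5), c(5, 5)), spec)),
               "PARTIAL_132_OPEN_124_CLOSED")
  expect_equal(as.character(classify_state(mk(c(2, 2), c(2, 5), c(5, 5)), spec)),
               "FULLY_CLOSED")
  ## boundary: exactly the ionic diameter is closed (strict inequality)
  b <- spec$ionic_diameter
  expect_equal(as.character(classify_state(mk(c(5, 5), c(5, 5), c(b, 5)), spec)),
               "GATE129_CLOSED")
  ## "either" rule: one open diametric pair suffices
  expect_equal(as.character(classify_state(mk(c(2, 5), c(5, 5), c(5, 5)), spec,
                                           rule = "either")),
               "FULLY_OPEN")
  ## two-gate spec: the 129 level is ignored
  spec2 <- channel_spec(secondary_gate = NULL)
  expect_equal(as.character(classify_state(mk(c(5, 5), c(5, 5), c(2, 2)), spec2)),
               "FULLY_OPEN")
})

test_that("classification is monotone in every distance", {
  rank_of <- c(FULLY_CLOSED = 0, PARTIAL_124_OPEN_132_CLOSED = 1,
               PARTIAL_132_OPEN_124_CLOSED = 1, GATE129_CLOSED = 2,
               FULLY_OPEN = 3)
  set.seed(17)
  for (rep in 1:200) {
    d <- runif(6, 1, 6)
    names(d) <- c("d124_AC", "d124_BD", "d132_AC", "d132_BD",
                  "d129_AC", "d129_BD")
    s1 <- as.character(classify_state(d, spec))
    k <- sample(6, 1)
    d2 <- d; d2[k] <- d2[k] + runif(1, 0, 4)
    s2 <- as.character(classify_state(d2, spec))
    expect_gte(rank_of[[s2]], rank_of[[s1]])
  }
})

test_that("population tables recover planted fractions and sum to 100", {
  ens10 <- make_ensemble(synthetic_params(
    n_frames = 10, state_probs = c(FULLY_OPEN = 1), seed = 1), spec)
  pt <- population_table(ens10, spec)
  expect_equal(pt$percentage[pt$state == "FULLY_OPEN"], 100)
  expect_equal(sum(pt$percentage), 100, tolerance = 0.1)

  ## planted mutant-style 52.8 / 47.2 split at n = 10000
  p <- synthetic_params(n_frames = 10000,
                        state_probs = reference_populations("S129R"),
                        seed = 4)
  ens <- make_ensemble(p, spec)
  pt <- population_table(ens, spec)
  expect_equal(sum(pt$percentage), 100, tolerance = 0.1)
  expect_lt(abs(pt$percentage[pt$state == "FULLY_OPEN"] - 52.8), 1.5)
  expect_lt(abs(pt$percentage[pt$state == "GATE129_CLOSED"] - 47.2), 1.5)
  ## classifier agrees with the generator labels frame by frame
  expect_identical(
    population_table(ens, spec)$count,
    population_table(ens, spec, use_labels = TRUE)$count)
})

test_that("distance series expose planted bimodality and degeneracy", {
  ## constant geometry: zero variance
  s <- default_channel()
  ens <- as_ensemble(rep(list(s), 4))
  ds <- distance_series(ens, 129, mode = "adjacent")
  expect_equal(stats::sd(ds$series$distance), 0)
  expect_equal(sort(unique(as.character(ds$series$pair))),
               c("129A-129B", "129B-129C", "129C-129D", "129D-129A"))

  ## bimodal adjacent 129-129 distances from a 50/50 open/129-closed mix
  p <- synthetic_params(n_frames = 400,
                        state_probs = c(FULLY_OPEN = 0.5,
                                        GATE129_CLOSED = 0.5), seed = 12)
  ens <- make_ensemble(p, spec)
  ds <- distance_series(ens, 129, mode = "adjacent", density = TRUE)
  dens <- ds$density
  ## the two construction centers: adjacent SC atoms at radius r are
  ## sqrt(2) r apart
  centers <- sqrt(2) * c(1.2, 4.0)
  peaks <- dens$x[which(diff(sign(diff(dens$y))) == -2) + 1]
  main <- sort(peaks[order(-dens$y[match(peaks, dens$x)])[1:2]])
  expect_equal(main, centers, tolerance = 0.2)
  ## mean/sd of the open sub-population propagates the coordinate noise
  op <- ds$series$distance[rep(ens$labels == "FULLY_OPEN", 4)]
  expect_equal(mean(op), sqrt(2) * 4.0, tolerance = 0.05)
  expect_equal(stats::sd(op), sqrt(2) * 0.15, tolerance = 0.05)
})
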