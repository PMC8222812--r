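## neighbour search shared by the Hessian builder and the potentials:
## all atom pairs (i < j) within the cutoff, with distances and unit
## separation vectors
.enm_pairs <- function(xyz, cutoff) {
  d <- as.matrix(stats::dist(xyz))
  pair <- which(upper.tri(d) & d > 0 & d <= cutoff, arr.ind = TRUE)
  if (nrow(pair) == 0L)
    stop("no atom pairs within the cutoff; cannot build a network")
  i <- pair[, 1]; j <- pair[, 2]
  dij <- d[pair]
  u <- (xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]) / dij
  list(i = i, j = j, d = dij, u = u)
}

#' Harmonic elastic-network potential
#'
#' Quadratic potential `U = (k/2) sum_pairs (u_ij . (dx_j - dx_i))^2` about
#' a reference structure, i.e. the anisotropic network model: every atom
#' pair within the cutoff is a Hookean spring penalizing changes of its
#' length to first order.  This is the default force provider for replica
#' and relaxation dynamics: it preserves the low-frequency collective
#' motions of the network while keeping force evaluation a single pass
#' over the spring list.
#'
#' @param structure reference `channel_structure`.
#' @param cutoff spring cutoff, Angstrom.
#' @param spring_k uniform force constant, kcal/mol/A^2.
#' @return an object of class `mdenm_potential`.
#' @export
enm_potential <- function(structure, cutoff = 12, spring_k = 1) {
  xyz <- coords(structure)
  p <- .enm_pairs(xyz, cutoff)
  base::structure(list(type = "enm", x0 = as_xyz(structure),
                       pi = p$i, pj = p$j, u = p$u, k = spring_k,
                       gate = NULL),
                  class = "mdenm_potential")
}

#' Elastic network with a double-well channel gate
#'
#' The open/close test fixture: the side-chain pseudo-atoms of one
#' constriction residue are decoupled from the elastic network and instead
#' feel a quartic double well along their chain's radial direction, with
#' minima at the closed and open gate radii and a barrier of `barrier`
#' kcal/mol at the midpoint, plus harmonic restraints (force constant
#' `k_perp`) on the tangential and axial directions.  All remaining atoms
#' feel the plain elastic network.  The gate can therefore switch between
#' the open and closed distance ranges without fighting network springs,
#' while the barrier separates the two basins on the timescale of
#' unexcited 300 K dynamics.
#'
#' @param structure reference `channel_structure`.
#' @param spec a [channel_spec()].
#' @param gate_residue constriction residue carrying the double well.
#' @param r_open,r_closed radial well positions, Angstrom.
#' @param barrier well-to-barrier height, kcal/mol.
#' @param k_perp tangential/axial restraint constant, kcal/mol/A^2.
#' @param cutoff,spring_k elastic-network parameters for the other atoms.
#' @return an `mdenm_potential` with an active gate term.
#' @export
double_well_potential <- function(structure, spec = channel_spec(),
                                  gate_residue = 129L, r_open = 4.0,
                                  r_closed = 1.2, barrier = 7,
                                  k_perp = 10, cutoff = 12, spring_k = 1) {
  a <- structure$atoms
  gate_idx <- which(a$resno == gate_residue & a$atom_name == "SC")
  if (length(gate_idx) == 0L)
    stop("no SC pseudo-atoms at residue ", gate_residue)
  xyz <- coords(structure)
  p <- .enm_pairs(xyz, cutoff)
  keep <- !(p$i %in% gate_idx | p$j %in% gate_idx)
  ## local frame per gate atom: radial unit u from the pore axis, the
  ## tangential unit, and the reference z
  pxy <- xyz[gate_idx, 1:2, drop = FALSE]
  r0 <- sqrt(rowSums(pxy^2))
  u <- pxy / r0
  gate <- list(idx = gate_idx, u = u, tang = cbind(-u[, 2], u[, 1]),
               z0 = xyz[gate_idx, 3],
               c = (r_open + r_closed) / 2, w = (r_open - r_closed) / 2,
               h = barrier, k_perp = k_perp)
  base::structure(list(type = "enm_double_well", x0 = as_xyz(structure),
                       pi = p$i[keep], pj = p$j[keep],
                       u = p$u[keep, , drop = FALSE], k = spring_k,
                       gate = gate),
                  class = "mdenm_potential")
}

#' Evaluate a potential
#'
#' @param potential an `mdenm_potential`.
#' @param x flat coordinate vector (x1, y1, z1, ...), Angstrom.
#' @return list with `energy` (kcal/mol) and `forces` (flat 3n vector,
#'   kcal/mol/A).
#' @export
potential_eval <- function(potential, x) {
  n <- length(potential$x0) / 3L
  dx <- matrix(x - potential$x0, ncol = 3, byrow = TRUE)
  rel <- dx[potential$pj, , drop = FALSE] - dx[potential$pi, , drop = FALSE]
  s <- potential$k * rowSums(potential$u * rel)
  e <- 0.5 * sum(s^2) / potential$k
  contrib <- potential$u * s
  f <- rowsum(rbind(contrib, -contrib),
              c(potential$pi, potential$pj), reorder = FALSE)
  fm <- matrix(0, n, 3)
  fm[as.integer(rownames(f)), ] <- f
  g <- potential$gate
  if (!is.null(g)) {
    gi <- g$idx
    xm <- matrix(x, ncol = 3, byrow = TRUE)
    sgate <- xm[gi, 1] * g$u[, 1] + xm[gi, 2] * g$u[, 2]
    q <- xm[gi, 1] * g$tang[, 1] + xm[gi, 2] * g$tang[, 2]
    dz <- xm[gi, 3] - g$z0
    sc <- sgate - g$c; w2 <- g$w^2
    e <- e + sum(g$h * (sc^2 - w2)^2 / w2^2 +
                 0.5 * g$k_perp * (q^2 + dz^2))
    dUds <- 4 * g$h * (sc^2 - w2) * sc / w2^2
    dUdq <- g$k_perp * q
    fm[gi, 1] <- fm[gi, 1] - dUds * g$u[, 1] - dUdq * g$tang[, 1]
    fm[gi, 2] <- fm[gi, 2] - dUds * g$u[, 2] - dUdq * g$tang[, 2]
    fm[gi, 3] <- fm[gi, 3] - g$k_perp * dz
  }
  list(energy = e, forces = as.numeric(t(fm)))
}

#' Radial breathing direction on gate atoms
#'
#' Unit displacement field pushing the side-chain pseudo-atoms of
#' `gate_residue` radially outward in all four chains and leaving every
#' other atom fixed; the planted "spherical opening" direction used by the
#' exploration fixtures.
#'
#' @param structure a `channel_structure`.
#' @param gate_residue constriction residue.
#' @return unit length-3n vector.
#' @export
breathing_direction <- function(structure, gate_residue = 129L) {
  a <- structure$atoms
  gi <- which(a$resno == gate_residue & a$atom_name == "SC")
  if (length(gi) == 0L)
    gi <- which(a$resno == gate_residue & a$atom_name == "CA")
  v <- numeric(3 * nrow(a))
  p <- as.matrix(a[gi, c("x", "y")])
  u <- p / sqrt(rowSums(p^2))
  v[3 * (gi - 1) + 1] <- u[, 1]
  v[3 * (gi - 1) + 2] <- u[, 2]
  v / sqrt(sum(v^2))
}
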