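## principal axis of a set of points, oriented from first to last point
.segment_axis <- function(xyz, method = c("principal", "endpoints")) {
  method <- match.arg(method)
  v <- if (method == "principal") {
    c0 <- sweep(xyz, 2, colMeans(xyz))
    svd(c0, nu = 0, nv = 1)$v[, 1]
  } else xyz[nrow(xyz), ] - xyz[1, ]
  span <- xyz[nrow(xyz), ] - xyz[1, ]
  if (sum(v * span) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' TM1 kink angle of one chain
#'
#' Angle between the axes of the two sub-segments of the outer helix: the
#' first from residue 46 to 56 and the second from 56 to 80.  Each axis is
#' the principal component of the sub-segment's CA coordinates, oriented
#' N-terminus to C-terminus, so a perfectly straight helix scores 0
#' degrees.  The measure depends only on internal geometry and is invariant
#' under rigid-body motion.
#'
#' @param structure a `channel_structure` (one chain, or use `chain`).
#' @param chain chain to measure; `NULL` measures every chain present.
#' @param seg1,seg2 inclusive residue intervals of the two sub-segments.
#' @param method `"principal"` (principal component of the segment CAs) or
#'   `"endpoints"` (first-to-last CA vector).
#' @return named numeric vector of kink angles in degrees, in \[0, 180\].
#' @export
kink_angle <- function(structure, chain = NULL, seg1 = c(46L, 56L),
                       seg2 = c(56L, 80L),
                       method = c("principal", "endpoints")) {
  method <- match.arg(method)
  chains <- chain %||% sort(unique(structure$atoms$chain))
  out <- vapply(chains, function(ch) {
    s1 <- select_atoms(structure, chain = ch, residues = seg1,
                       atom_names = "CA")
    s2 <- select_atoms(structure, chain = ch, residues = seg2,
                       atom_names = "CA")
    if (n_atoms(s1) < 2L || n_atoms(s2) < 2L)
      stop("chain ", ch, " is missing residues ", seg1[1], "-", seg2[2])
    a1 <- .segment_axis(coords(s1), method)
    a2 <- .segment_axis(coords(s2), method)
    .rad2deg(acos(max(-1, min(1, sum(a1 * a2)))))
  }, numeric(1))
  names(out) <- chains
  out
}

## signed dihedral of four points, degrees in (-180, 180]
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  .rad2deg(ang)
}

#' Cytoplasmic-domain rotation angle of one chain
#'
#' Pseudo-dihedral of four points: the CA of an inner reference residue
#' (Leu108), its orthogonal projection on the central pore axis, the
#' projection of a cytoplasmic-domain residue's CA (Ile266), and that CA
#' itself.  It measures how far the cytoplasmic domain is twisted about
#' the pore axis relative to the transmembrane core; rotating the domain
#' by theta about the axis shifts the angle by exactly theta.
#'
#' @param structure a `channel_structure`.
#' @param chain chain to measure; `NULL` measures every chain present.
#' @param res_inner,res_outer residue numbers of the two reference CAs.
#' @param axis pore axis direction (default z).
#' @param origin a point on the axis.
#' @return named numeric vector of angles in degrees, in (-180, 180].
#' @export
ctd_rotation <- function(structure, chain = NULL, res_inner = 108L,
                         res_outer = 266L, axis = c(0, 0, 1),
                         origin = c(0, 0, 0)) {
  a <- axis / sqrt(sum(axis^2))
  chains <- chain %||% sort(unique(structure$atoms$chain))
  out <- vapply(chains, function(ch) {
    p1 <- as.numeric(coords(select_atoms(structure, chain = ch,
                                         residues = c(res_inner, res_inner),
                                         atom_names = "CA"))[1, ])
    p4 <- as.numeric(coords(select_atoms(structure, chain = ch,
                                         residues = c(res_outer, res_outer),
                                         atom_names = "CA"))[1, ])
    proj <- function(p) origin + sum((p - origin) * a) * a
    p2 <- proj(p1); p3 <- proj(p4)
    if (sqrt(sum((p1 - p2)^2)) < 1e-9 || sqrt(sum((p4 - p3)^2)) < 1e-9)
      stop("reference CA lies on the pore axis; dihedral undefined")
    dihedral_angle(p1, p2, p3, p4)
  }, numeric(1))
  names(out) <- chains
  out
}

#' Per-residue ensemble RMSD
#'
#' For each atom i, `RMSD_i = sqrt(mean_n |r_i(n) - r_i^ref|^2)` over the
#' N frames of the ensemble; the residue value is the average of its
#' atoms' RMSD_i.  No superposition is applied unless requested, and the
#' choice is recorded in the result.
#'
#' @param ensemble a `channel_ensemble`.
#' @param reference a `channel_structure` sharing the ensemble topology, or
#'   `"mean"` for the ensemble average structure.
#' @param superpose fit each frame to the reference on CA atoms first?
#' @return data frame `chain`, `resno`, `rmsd` (Angstrom), with attributes
#'   `superposed` and `reference`.
#' @export
per_residue_rmsd <- function(ensemble, reference = "mean",
                             superpose = FALSE) {
  topo <- ensemble$topology
  xyz <- ensemble$xyz
  ref <- if (identical(reference, "mean")) colMeans(xyz)
  else {
    if (!inherits(reference, "channel_structure"))
      stop("reference must be a channel_structure or \"mean\"")
    if (n_atoms(reference) != nrow(topo))
      stop("reference topology does not match the ensemble (",
           n_atoms(reference), " vs ", nrow(topo), " atoms)")
    as_xyz(reference)
  }
  if (superpose) {
    fit_atoms <- which(topo$atom_name == "CA")
    if (length(fit_atoms) < 3L) fit_atoms <- seq_len(nrow(topo))
    refm <- matrix(ref, ncol = 3, byrow = TRUE)
    for (i in seq_len(nrow(xyz))) {
      xi <- .row_xyz(xyz, i)
      f <- kabsch(xi[fit_atoms, , drop = FALSE],
                  refm[fit_atoms, , drop = FALSE])
      xyz[i, ] <- as.numeric(t(.apply_fit(xi, f)))
    }
  }
  dev2 <- sweep(xyz, 2, ref)^2
  ## per-atom mean squared deviation over frames, summed over x,y,z
  msd_atom <- colMeans(dev2)
  msd_atom <- msd_atom[c(TRUE, FALSE, FALSE)] + msd_atom[c(FALSE, TRUE, FALSE)] +
    msd_atom[c(FALSE, FALSE, TRUE)]
  rmsd_atom <- sqrt(msd_atom)
  key <- paste(topo$chain, topo$resno)
  agg <- tapply(rmsd_atom, key, mean)
  ord <- unique(key)
  out <- data.frame(chain = topo$chain[!duplicated(key)],
                    resno = topo$resno[!duplicated(key)],
                    rmsd = as.numeric(agg[ord]))
  attr(out, "superposed") <- superpose
  attr(out, "reference") <- if (identical(reference, "mean"))
    "ensemble mean" else "supplied structure"
  out
}

#' Simplified pore-radius profile
#'
#' At each z-grid point, the pore radius is the minimum over the atoms of
#' the surrounding z-slab of (distance of the atom to the pore axis minus
#' its radius), floored at zero.  This is a fast stand-in for full
#' sphere-maximization profilers: it assumes the pore axis is z and reports
#' the tightest constriction per slab.
#'
#' @param structure a `channel_structure` with its pore on the z axis.
#' @param z_grid grid of z values (default: 1 A steps over the structure's
#'   z range).
#' @param atom_radii scalar or per-atom radii, Angstrom (default 0:
#'   pseudo-atom centers).
#' @param slab slab thickness around each grid point, Angstrom.
#' @return data frame `z`, `radius` (NA where the slab is empty),
#'   `n_atoms`; class `pore_profile`.
#' @export
pore_radius_profile <- function(structure, z_grid = NULL, atom_radii = 0,
                                slab = 1) {
  xyz <- coords(structure)
  if (is.null(z_grid))
    z_grid <- seq(floor(min(xyz[, 3])), ceiling(max(xyz[, 3])), by = 1)
  radii <- rep(atom_radii, length.out = nrow(xyz))
  raxis <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  out <- data.frame(z = z_grid, radius = NA_real_, n_atoms = 0L)
  for (k in seq_along(z_grid)) {
    in_slab <- abs(xyz[, 3] - z_grid[k]) <= slab / 2
    out$n_atoms[k] <- sum(in_slab)
    if (any(in_slab))
      out$radius[k] <- max(0, min(raxis[in_slab] - radii[in_slab]))
  }
  class(out) <- c("pore_profile", "data.frame")
  out
}

#' @export
plot.pore_profile <- function(x, ...) {
  graphics::plot(x$radius, x$z, type = "l", lwd = 2,
                 xlab = "pore radius (A)", ylab = "z (A)",
                 main = "Pore radius profile", ...)
  invisible(x)
}


#' Estimate the pore axis from the four-fold symmetry
#'
#' For a tetramer whose chains share one topology, the axis is estimated
#' from the chain centroids: the origin is their mean and the direction is
#' the normal of the plane spanned by the two diagonals (centroid A minus
#' centroid C, and B minus D), oriented towards +z.  Useful for inputs that
#' are not already aligned with the z convention; the result can be passed
#' to [ctd_rotation()], or used to rotate the structure onto z with
#' [transform_structure()].
#'
#' @param structure a four-chain `channel_structure`.
#' @param chains the four chain ids in diagonal order (A,C) and (B,D).
#' @return list with unit `axis` and `origin`.
#' @export
estimate_pore_axis <- function(structure, chains = c("A", "B", "C", "D")) {
  cent <- vapply(chains, function(ch)
    colMeans(coords(select_atoms(structure, chain = ch))), numeric(3))
  origin <- rowMeans(cent)
  ax <- as.numeric(cross3(cent[, 1] - cent[, 3], cent[, 2] - cent[, 4]))
  nrm <- sqrt(sum(ax^2))
  if (nrm < 1e-9)
    stop("chain centroids are collinear; cannot estimate an axis")
  ax <- ax / nrm
  if (ax[3] < 0) ax <- -ax
  list(axis = ax, origin = as.numeric(origin))
}

#' Ensemble geometry report
#'
#' Per-frame, per-chain TM1 kink and cytoplasmic-domain rotation angles,
#' per-residue RMSD, and summary statistics (mean, median, sd) per chain.
#'
#' @param ensemble a `channel_ensemble`.
#' @param reference reference for [per_residue_rmsd()].
#' @param axis,origin pore axis for [ctd_rotation()].
#' @return object of class `geometry_report`: `$angles` (long data frame
#'   frame/chain/metric/value), `$summary` (per chain and metric),
#'   `$rmsd_per_residue`.
#' @export
geometry_report <- function(ensemble, reference = "mean",
                            axis = c(0, 0, 1), origin = c(0, 0, 0)) {
  nf <- n_frames(ensemble)
  rows <- vector("list", nf)
  for (i in seq_len(nf)) {
    s <- ensemble_frame(ensemble, i)
    kk <- kink_angle(s)
    rr <- ctd_rotation(s, axis = axis, origin = origin)
    rows[[i]] <- rbind(
      data.frame(frame = i, chain = names(kk), metric = "kink_deg",
                 value = as.numeric(kk)),
      data.frame(frame = i, chain = names(rr), metric = "rotation_deg",
                 value = as.numeric(rr)))
  }
  angles <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(angles, angles[c("chain", "metric")]),
    function(g) data.frame(chain = g$chain[1], metric = g$metric[1],
                           mean = mean(g$value),
                           median = stats::median(g$value),
                           sd = stats::sd(g$value))))
  rownames(summ) <- NULL
  structure(list(angles = angles, summary = summ,
                 rmsd_per_residue = per_residue_rmsd(ensemble, reference)),
            class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("geometry_report over", max(x$angles$frame), "frames\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
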