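#' Build an anisotropic elastic-network Hessian
#'
#' Standard anisotropic network model: every atom pair within `cutoff` is
#' joined by a Hookean spring of uniform force constant, giving 3x3
#' off-diagonal blocks `-k/d^2 * r_ij r_ij^T` and diagonal blocks that
#' enforce the translational sum rule exactly.  With `masses` supplied the
#' Hessian is mass-weighted (`M^{-1/2} H M^{-1/2}`), so eigenvalues are
#' squared angular frequencies.
#'
#' @param structure a `channel_structure`.
#' @param cutoff interaction cutoff, Angstrom.
#' @param spring_k uniform spring constant (kcal/mol/A^2).
#' @param masses optional per-atom masses (amu) for mass weighting; `TRUE`
#'   uses the structure's own masses.
#' @param sparse return a `Matrix::dgCMatrix` instead of a dense matrix?
#' @return symmetric `3n x 3n` Hessian with attributes `cutoff`, `spring_k`,
#'   `mass_weighted`, `masses` and `n_components` (a disconnected network
#'   triggers a warning with the component count).
#' @export
build_hessian <- function(structure, cutoff = 12, spring_k = 1,
                          masses = NULL, sparse = FALSE) {
  xyz <- coords(structure)
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  pair <- which(upper.tri(d) & d > 0 & d <= cutoff, arr.ind = TRUE)
  if (nrow(pair) == 0L)
    stop("no atom pairs within the cutoff; cannot build a network")
  i <- pair[, 1]; j <- pair[, 2]
  rij <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
  dij2 <- d[pair]^2

  ## connectivity check (union-find over spring pairs)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (k in seq_along(i)) {
    ra <- find(i[k]); rb <- find(j[k])
    if (ra != rb) parent[ra] <- rb
  }
  ncomp <- length(unique(vapply(seq_len(n), find, integer(1))))
  if (ncomp > 1L)
    warning("elastic network is disconnected: ", ncomp, " components")

  ## 9 triplet entries per pair per triangle; duplicates in sparseMatrix sum
  ab <- expand.grid(a = 1:3, b = 1:3)
  np <- length(i)
  ti <- tj <- tx <- vector("list", 9)
  for (q in seq_len(9)) {
    a <- ab$a[q]; b <- ab$b[q]
    blk <- -spring_k * rij[, a] * rij[, b] / dij2
    ti[[q]] <- c(3 * (i - 1) + a, 3 * (j - 1) + a, 3 * (i - 1) + a, 3 * (j - 1) + a)
    tj[[q]] <- c(3 * (j - 1) + b, 3 * (i - 1) + b, 3 * (i - 1) + b, 3 * (j - 1) + b)
    tx[[q]] <- c(blk, blk, -blk, -blk)
  }
  H <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(3 * n, 3 * n))
  H <- Matrix::forceSymmetric((H + Matrix::t(H)) / 2)
  mass_weighted <- FALSE
  mvec <- NULL
  if (!is.null(masses)) {
    mvec <- if (isTRUE(masses)) atom_masses(structure) else rep(masses, length.out = n)
    s <- 1 / sqrt(rep(mvec, each = 3))
    H <- Matrix::Diagonal(x = s) %*% H %*% Matrix::Diagonal(x = s)
    H <- Matrix::forceSymmetric(H)
    mass_weighted <- TRUE
  }
  out <- if (sparse)
    methods::as(methods::as(H, "generalMatrix"), "CsparseMatrix")
  else as.matrix(H)
  attr(out, "cutoff") <- cutoff
  attr(out, "spring_k") <- spring_k
  attr(out, "mass_weighted") <- mass_weighted
  attr(out, "masses") <- mvec
  attr(out, "n_components") <- ncomp
  out
}

#' Compute the lowest-frequency normal modes
#'
#' Dense eigendecomposition of a symmetric (optionally mass-weighted)
#' network Hessian.  Modes are returned in ascending order of eigenvalue;
#' for a connected network the six rigid-body modes have eigenvalues at
#' numerical zero and are flagged so downstream selection can skip them.
#'
#' @param hessian symmetric matrix from [build_hessian()].
#' @param n_modes number of lowest modes to keep (default 200, capped at
#'   the matrix size).
#' @param zero_tol relative tolerance flagging rigid-body (zero) modes, as
#'   a fraction of the largest eigenvalue magnitude.
#' @return an object of class `mode_set` with orthonormal `vectors`
#'   (3n x n_modes), ascending `values`, `frequencies` (sqrt of clamped
#'   eigenvalues, arbitrary units unless mass-weighted), logical `zero`,
#'   and `mass_weighted`/`masses` carried from the Hessian.
#' @export
compute_modes <- function(hessian, n_modes = 200L, zero_tol = 1e-8) {
  hessian_dense <- as.matrix(hessian)
  nd <- nrow(hessian_dense)
  if (n_modes > nd)
    stop("n_modes (", n_modes, ") exceeds matrix size (", nd, ")")
  e <- eigen(hessian_dense, symmetric = TRUE)
  ord <- rev(seq_len(nd))            # ascending eigenvalues
  values <- e$values[ord][seq_len(n_modes)]
  vectors <- e$vectors[, ord, drop = FALSE][, seq_len(n_modes), drop = FALSE]
  vmax <- max(abs(e$values))
  zero <- abs(values) < zero_tol * vmax
  structure(list(vectors = vectors, values = values,
                 frequencies = sqrt(pmax(values, 0)),
                 zero = zero,
                 mass_weighted = isTRUE(attr(hessian, "mass_weighted")),
                 masses = attr(hessian, "masses"),
                 selection = NULL),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat("mode_set:", ncol(x$vectors), "modes (", sum(x$zero), "rigid-body ),",
      if (x$mass_weighted) "mass-weighted" else "unweighted", "\n")
  if (!is.null(x$selection)) {
    cat("  selected:", sum(x$selection$selected), "gating mode(s)\n")
    print(x$selection[x$selection$selected, , drop = FALSE])
  }
  invisible(x)
}

## Cartesian displacement field of one mode (un-mass-weights if needed)
.mode_cartesian <- function(modes, k) {
  v <- modes$vectors[, k]
  if (modes$mass_weighted && !is.null(modes$masses))
    v <- v / sqrt(rep(modes$masses, each = 3))
  v
}

#' Displace a structure along a mode vector to a target RMSD
#'
#' Scales the (mass-unweighted) displacement field so that the all-atom
#' RMSD between the displaced and input structures equals `target_rmsd`
#' exactly.
#'
#' @param structure a `channel_structure`.
#' @param mode a length-3n displacement vector, or a `mode_set` plus
#'   `mode_index`.
#' @param target_rmsd Angstrom.
#' @param sign +1 or -1, direction of displacement.
#' @param mode_index column of the `mode_set` to use.
#' @return the displaced `channel_structure`.
#' @export
displace_along <- function(structure, mode, target_rmsd, sign = 1,
                           mode_index = 1L) {
  v <- if (inherits(mode, "mode_set")) .mode_cartesian(mode, mode_index)
       else as.numeric(mode)
  n <- n_atoms(structure)
  if (length(v) != 3L * n)
    stop("mode vector length ", length(v), " does not match 3 x ", n, " atoms")
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("mode vector is zero")
  scale <- sign * target_rmsd * sqrt(n) / nv
  coords(structure) <- as_xyz(structure) + scale * v
  structure
}

## diametric probe-residue distances for the two gate pairs
.probe_distances <- function(structure, spec, probe_residue) {
  vapply(spec$gate_pairs, function(p)
    shortest_distance(structure,
                      list(resno = probe_residue, chain = p[1]),
                      list(resno = probe_residue, chain = p[2])),
    numeric(1))
}

#' Select channel-gating normal modes
#'
#' Applies the gating-mode selection protocol: each non-rigid mode is used
#' to displace the structure by `displace_rmsd` in both directions; its
#' channel score is the largest absolute change of the diametric
#' probe-residue (default 125) pair distances between the two displaced
#' structures.  The `n_keep_first` highest-scoring modes are retained and
#' classified by the signed pair-distance changes at +`displace_rmsd`:
#' both pairs widening (or narrowing) comparably is a spherical
#' opening, a strongly anisotropic or opposite-signed change is elliptical,
#' anything below the noise floor is dropped.  Redundant modes (cosine
#' similarity of channel-region displacement patterns above
#' `redundancy_cos`) are pruned keeping the lower-frequency mode, and the
#' `n_final` lowest-frequency survivors are marked selected.
#'
#' @param modes a `mode_set`.
#' @param structure the reference `channel_structure`.
#' @param spec a [channel_spec()].
#' @param probe_residue residue whose diametric distances probe the channel.
#' @param n_keep_first modes retained by channel score.
#' @param n_final modes finally selected (fewer survivors gives a warning).
#' @param displace_rmsd displacement amplitude used for scoring, Angstrom.
#' @param spherical_ratio min/max |change| ratio separating spherical from
#'   elliptical same-sign patterns.
#' @param noise_floor Angstrom; changes below it carry no shape information.
#' @param redundancy_cos cosine-similarity threshold for redundancy.
#' @return the `mode_set` with a `selection` data frame (one row per
#'   non-rigid mode: channel score, shape class, selected flag).
#' @export
select_gating_modes <- function(modes, structure, spec = channel_spec(),
                                probe_residue = 125L, n_keep_first = 10L,
                                n_final = 4L, displace_rmsd = 2,
                                spherical_ratio = 0.5, noise_floor = 0.1,
                                redundancy_cos = 0.9) {
  cand <- which(!modes$zero)
  if (length(cand) < n_keep_first)
    stop("need at least ", n_keep_first, " non-rigid modes, have ",
         length(cand))
  d0 <- .probe_distances(structure, spec, probe_residue)
  score <- numeric(length(cand))
  delta_plus <- matrix(NA_real_, length(cand), 2)
  for (q in seq_along(cand)) {
    k <- cand[q]
    dp <- .probe_distances(displace_along(structure, modes, displace_rmsd,
                                          +1, mode_index = k),
                           spec, probe_residue)
    dm <- .probe_distances(displace_along(structure, modes, displace_rmsd,
                                          -1, mode_index = k),
                           spec, probe_residue)
    score[q] <- max(abs(dp - dm))
    delta_plus[q, ] <- dp - d0
  }
  top <- cand[order(score, decreasing = TRUE)[seq_len(n_keep_first)]]
  shape <- vapply(match(top, cand), function(q) {
    dl <- delta_plus[q, ]
    big <- abs(dl) > noise_floor
    if (!any(big)) return("other")
    if (prod(sign(dl)) > 0) {
      if (min(abs(dl)) / max(abs(dl)) >= spherical_ratio) "spherical"
      else "elliptical"
    } else if (all(big)) "elliptical" else "other"
  }, character(1))

  keep <- top[shape != "other"]
  keep_shape <- shape[shape != "other"]
  ## redundancy pruning on channel-region sub-vectors, lower frequency wins
  region_atoms <- which(structure$atoms$resno >= spec$channel_range[1] &
                        structure$atoms$resno <= spec$channel_range[2])
  ridx <- as.vector(t(outer(3 * (region_atoms - 1), 1:3, "+")))
  ord <- order(modes$values[keep])
  keep <- keep[ord]; keep_shape <- keep_shape[ord]
  surv <- logical(length(keep))
  for (q in seq_along(keep)) {
    vq <- modes$vectors[ridx, keep[q]]
    redundant <- FALSE
    for (p in which(surv)) {
      vp <- modes$vectors[ridx, keep[p]]
      cs <- abs(sum(vq * vp)) / (sqrt(sum(vq^2)) * sqrt(sum(vp^2)))
      if (is.finite(cs) && cs > redundancy_cos) { redundant <- TRUE; break }
    }
    surv[q] <- !redundant
  }
  final <- keep[surv][seq_len(min(n_final, sum(surv)))]
  if (length(final) < n_final)
    warning("only ", length(final), " gating modes survive selection (",
            n_final, " requested)")
  sel <- data.frame(mode = cand,
                    frequency = modes$frequencies[cand],
                    channel_score = score,
                    shape = NA_character_,
                    selected = cand %in% final,
                    stringsAsFactors = FALSE)
  sel$shape[match(top, cand)] <- shape
  modes$selection <- sel
  modes
}

#' Indices of the selected gating modes
#' @param modes a `mode_set` after [select_gating_modes()].
#' @return integer mode indices.
#' @export
selected_modes <- function(modes) {
  if (is.null(modes$selection)) stop("run select_gating_modes() first")
  modes$selection$mode[modes$selection$selected]
}

#' Serialize a mode set to plain-text files
#'
#' Writes `<prefix>_values.csv` (mode, eigenvalue, frequency, zero flag),
#' `<prefix>_vectors.csv` (one column per mode) and, when present,
#' `<prefix>_selection.csv`.
#'
#' @param modes a `mode_set`.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_mode_set <- function(modes, prefix) {
  utils::write.csv(data.frame(mode = seq_along(modes$values),
                              eigenvalue = modes$values,
                              frequency = modes$frequencies,
                              zero = modes$zero),
                   paste0(prefix, "_values.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(modes$vectors),
                   paste0(prefix, "_vectors.csv"), row.names = FALSE)
  if (!is.null(modes$selection))
    utils::write.csv(modes$selection, paste0(prefix, "_selection.csv"),
                     row.names = FALSE)
  invisible(prefix)
}

#' Read a mode set written by [write_mode_set()]
#' @param prefix path prefix used when writing.
#' @return a `mode_set`.
#' @export
read_mode_set <- function(prefix) {
  vals <- utils::read.csv(paste0(prefix, "_values.csv"))
  vecs <- as.matrix(utils::read.csv(paste0(prefix, "_vectors.csv")))
  dimnames(vecs) <- NULL
  sel_path <- paste0(prefix, "_selection.csv")
  structure(list(vectors = vecs, values = vals$eigenvalue,
                 frequencies = vals$frequency, zero = vals$zero,
                 mass_weighted = FALSE, masses = NULL,
                 selection = if (file.exists(sel_path))
                   utils::read.csv(sel_path) else NULL),
            class = "mode_set")
}
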