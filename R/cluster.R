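## Kabsch least-squares superposition: rotation + translation mapping the
## rows of `mobile` onto `fixed` (both k x 3, same k).
kabsch <- function(mobile, fixed) {
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = R, t_mobile = cm, t_fixed = cf)
}

## apply a kabsch fit (computed on fit atoms) to full n x 3 coordinates
.apply_fit <- function(xyz, fit) {
  sweep(sweep(xyz, 2, fit$t_mobile) %*% fit$rotation, 2, fit$t_fixed, "+")
}

rmsd_xyz <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

## frame i of a flat-row coordinate matrix as n x 3
.row_xyz <- function(xyz, i) matrix(xyz[i, ], ncol = 3, byrow = TRUE)

#' Greedy leader clustering on the channel region
#'
#' Clusters an ensemble by channel-region RMSD with the leader algorithm:
#' the first frame seeds cluster 1, and every subsequent frame joins the
#' nearest existing leader if within `threshold`, otherwise it seeds a new
#' cluster (singletons therefore survive as their own clusters).  By
#' default each frame is first superposed on the leader with a
#' whole-structure CA fit so the region RMSD reflects internal channel
#' geometry rather than rigid drift; `superpose = FALSE` measures RMSD in
#' the common pore-axis frame instead.  After assignment, each cluster's
#' representative is the member closest (region RMSD) to the cluster's
#' average structure.
#'
#' @param ensemble a `channel_ensemble`.
#' @param region inclusive residue interval defining the channel (default
#'   121-133); all atoms of those residues in all chains are used.
#' @param threshold Angstrom (default 0.9).
#' @param superpose fit frames on CA atoms before the region RMSD?
#' @return an object of class `channel_clustering`: `assignments` (frame to
#'   cluster id), `representatives` (cluster id to frame index),
#'   `threshold`, `region`, `superposed`.
#' @export
cluster_frames <- function(ensemble, region = c(121L, 133L), threshold = 0.9,
                           superpose = TRUE) {
  topo <- ensemble$topology
  region_atoms <- which(topo$resno >= region[1] & topo$resno <= region[2])
  if (length(region_atoms) == 0L)
    stop("no atoms in residue interval ", region[1], "-", region[2])
  fit_atoms <- which(topo$atom_name == "CA")
  if (length(fit_atoms) < 3L) fit_atoms <- seq_len(nrow(topo))
  nf <- n_frames(ensemble)

  fitted_region <- function(i, leader_xyz_fit) {
    xi <- .row_xyz(ensemble$xyz, i)
    if (superpose) {
      f <- kabsch(xi[fit_atoms, , drop = FALSE], leader_xyz_fit)
      .apply_fit(xi, f)[region_atoms, , drop = FALSE]
    } else xi[region_atoms, , drop = FALSE]
  }

  leaders <- integer(0)
  assignments <- integer(nf)
  leader_fit <- list(); leader_region <- list()
  for (i in seq_len(nf)) {
    if (length(leaders)) {
      dists <- vapply(seq_along(leaders), function(L)
        rmsd_xyz(fitted_region(i, leader_fit[[L]]), leader_region[[L]]),
        numeric(1))
      L <- which.min(dists)
    }
    if (!length(leaders) || dists[L] > threshold) {
      leaders <- c(leaders, i)
      L <- length(leaders)
      xi <- .row_xyz(ensemble$xyz, i)
      leader_fit[[L]] <- xi[fit_atoms, , drop = FALSE]
      leader_region[[L]] <- xi[region_atoms, , drop = FALSE]
    }
    assignments[i] <- L
  }

  ## representative: member minimizing region RMSD to the cluster average
  representatives <- integer(length(leaders))
  for (L in seq_along(leaders)) {
    members <- which(assignments == L)
    reg <- lapply(members, function(i) fitted_region(i, leader_fit[[L]]))
    avg <- Reduce(`+`, reg) / length(reg)
    d2avg <- vapply(reg, function(x) rmsd_xyz(x, avg), numeric(1))
    representatives[L] <- members[which.min(d2avg)]
  }
  structure(list(assignments = assignments,
                 representatives = representatives,
                 threshold = threshold, region = as.integer(region),
                 superposed = superpose),
            class = "channel_clustering")
}

#' @export
print.channel_clustering <- function(x, ...) {
  sizes <- table(x$assignments)
  cat("channel_clustering:", length(x$representatives), "clusters over",
      length(x$assignments), "frames (threshold", x$threshold,
      "A on residues", x$region[1], "-", x$region[2], ")\n")
  cat("  singletons:", sum(sizes == 1), "  largest:", max(sizes), "\n")
  invisible(x)
}

#' @export
as.data.frame.channel_clustering <- function(x, ...) {
  data.frame(frame = seq_along(x$assignments),
             cluster = x$assignments,
             is_representative =
               seq_along(x$assignments) %in% x$representatives)
}

#' Extract representative structures
#' @param ensemble the clustered `channel_ensemble`.
#' @param clustering a `channel_clustering`.
#' @return list of `channel_structure`s, one per cluster.
#' @export
cluster_representatives <- function(ensemble, clustering) {
  lapply(clustering$representatives, function(i) ensemble_frame(ensemble, i))
}

## frames kept after discarding the leading (1 - keep_fraction): drop the
## first ceiling((1 - keep)*n), keep the rest
.kept_frames <- function(n, keep_fraction) {
  drop_n <- ceiling((1 - keep_fraction) * n)
  if (drop_n <= 0L) seq_len(n) else seq.int(drop_n + 1L, n)
}

#' Relax representative structures and keep the tail of each trajectory
#'
#' Runs unexcited Langevin dynamics from each representative to release the
#' kinetic energy accumulated during excitation, then discards the first
#' quarter (by default) of each trajectory and concatenates the remainder
#' with per-frame provenance.
#'
#' @param representatives list of `channel_structure`s (or a single one).
#' @param potential an `mdenm_potential`.
#' @param duration ps of free dynamics per representative (0.4 ns in the
#'   production protocol; scale down for toy runs).
#' @param keep_fraction fraction of each trajectory retained, from the end.
#' @param config an [excitation_config()] providing timestep, friction,
#'   bath temperature, record stride and base seed.
#' @return a `channel_ensemble` of the kept frames with attributes
#'   `provenance` (data frame: representative, frame, step) and
#'   `kinetic_temperature` (per kept frame).  A representative whose
#'   dynamics go non-finite is dropped with a warning; the others proceed.
#' @export
relax <- function(representatives, potential, duration = 400,
                  keep_fraction = 0.75, config = excitation_config()) {
  if (inherits(representatives, "channel_structure"))
    representatives <- list(representatives)
  stopifnot(duration > 0, keep_fraction > 0, keep_fraction <= 1)
  n_steps <- round(duration / config$timestep)
  frames <- list(); prov <- list(); temps <- list()
  for (k in seq_along(representatives)) {
    s <- representatives[[k]]
    masses <- atom_masses(s)
    set.seed(config$seed + k)
    out <- tryCatch(
      .langevin(as_xyz(s), maxwell_velocities(masses, config$bath_temperature),
                masses, potential, n_steps, config$timestep, config$friction,
                config$bath_temperature, config$record_stride),
      error = function(e) {
        warning("representative ", k, " dropped: ", conditionMessage(e))
        NULL
      })
    if (is.null(out)) next
    nrec <- nrow(out$frames)
    kept <- .kept_frames(nrec, keep_fraction)
    frames[[length(frames) + 1L]] <- out$frames[kept, , drop = FALSE]
    temps[[length(temps) + 1L]] <- out$temps[kept]
    prov[[length(prov) + 1L]] <- data.frame(representative = k,
                                            frame = kept,
                                            step = out$steps[kept])
  }
  if (!length(frames)) stop("all representatives failed to relax")
  ens <- channel_ensemble(representatives[[1]]$atoms, do.call(rbind, frames),
                          source = sprintf("relax(%d reps, %.3g ps, keep %.2f)",
                                           length(representatives), duration,
                                           keep_fraction))
  attr(ens, "provenance") <- do.call(rbind, prov)
  attr(ens, "kinetic_temperature") <- unlist(temps)
  ens
}
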