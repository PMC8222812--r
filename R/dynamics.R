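#' Configuration of a replica-excitation run
#'
#' Protocol constants of the MDeNM excitation scheme.  Defaults are the
#' standard protocol: 10 successive excitations per replica, each injecting
#' the kinetic energy of a 4 K rise of the overall temperature, separated by
#' a 1 ps relaxation interval, with a 300 K Langevin bath; mode
#' combinations are compared through structures displaced to 1 Angstrom
#' RMSD.  62 replicas is a typical production count (66 was used for the
#' S129R system); toy-scale runs use far fewer.
#'
#' @param n_replicas number of excitation directions / replicas.
#' @param n_excitations kinetic-energy injections per replica.
#' @param delta_T temperature rise per excitation, Kelvin.
#' @param relaxation_time interval between excitations, ps.
#' @param combination_probe_rmsd displacement (Angstrom) at which direction
#'   spacing is measured.
#' @param timestep integration step, ps.
#' @param bath_temperature Langevin bath temperature, Kelvin.
#' @param friction Langevin friction, 1/ps.
#' @param record_stride store a frame every this many steps.
#' @param seed base RNG seed; replica `k` uses `seed + k`.
#' @return an object of class `excitation_config`.
#' @export
excitation_config <- function(n_replicas = 62L, n_excitations = 10L,
                              delta_T = 4, relaxation_time = 1,
                              combination_probe_rmsd = 1,
                              timestep = 0.002, bath_temperature = 300,
                              friction = 1, record_stride = 50L,
                              seed = 1L) {
  vals <- c(n_replicas, relaxation_time, combination_probe_rmsd, timestep,
            bath_temperature, friction, record_stride)
  if (any(vals <= 0)) stop("all configuration values must be positive")
  if (delta_T < 0) stop("delta_T must be non-negative")
  if (n_excitations < 1) stop("n_excitations must be at least 1")
  structure(list(n_replicas = as.integer(n_replicas),
                 n_excitations = as.integer(n_excitations),
                 delta_T = delta_T, relaxation_time = relaxation_time,
                 combination_probe_rmsd = combination_probe_rmsd,
                 timestep = timestep, bath_temperature = bath_temperature,
                 friction = friction,
                 record_stride = as.integer(record_stride),
                 seed = as.integer(seed)),
            class = "excitation_config")
}

#' Maxwell-Boltzmann velocities
#' @param masses per-atom masses, amu.
#' @param temperature Kelvin.
#' @return flat 3n velocity vector, Angstrom/ps.
#' @export
maxwell_velocities <- function(masses, temperature) {
  m3 <- rep(masses, each = 3)
  stats::rnorm(length(m3), sd = sqrt(.kB * temperature * .E_CONV / m3))
}

#' Kinetic energy and instantaneous temperature
#' @param velocities flat 3n vector, Angstrom/ps.
#' @param masses per-atom masses, amu.
#' @return kinetic energy in kcal/mol.
#' @export
kinetic_energy <- function(velocities, masses) {
  0.5 * sum(rep(masses, each = 3) * velocities^2) / .E_CONV
}

#' @rdname kinetic_energy
#' @return `kinetic_temperature`: Kelvin, using 3n degrees of freedom.
#' @export
kinetic_temperature <- function(velocities, masses) {
  n <- length(masses)
  2 * kinetic_energy(velocities, masses) / (3 * n * .kB)
}

#' Inject excitation velocities along a direction
#'
#' Adds a velocity increment proportional to `direction`, scaled so the
#' kinetic energy of the increment alone equals the energy of a `delta_T`
#' rise of the overall temperature: `(3/2) n_atoms kB delta_T`.
#'
#' @param velocities current flat 3n velocities, Angstrom/ps.
#' @param masses per-atom masses, amu.
#' @param direction flat 3n direction (normalized internally; zero is an
#'   error).
#' @param delta_T Kelvin.
#' @return updated velocities.
#' @export
excite <- function(velocities, masses, direction, delta_T) {
  if (sqrt(sum(direction^2)) == 0) stop("excitation direction is zero")
  if (delta_T == 0) return(velocities)
  n <- length(masses)
  m3 <- rep(masses, each = 3)
  e_target <- 1.5 * n * .kB * delta_T           # kcal/mol
  alpha <- sqrt(2 * e_target * .E_CONV / sum(m3 * direction^2))
  velocities + alpha * direction
}

## BAOAB Langevin integrator over an mdenm_potential.  Excitations (if
## any) are applied before the step whose index appears in excite_steps
## (0-based).  Frames and on-step kinetic temperatures are recorded every
## record_stride steps (plus the initial state).  The inner loop runs in
## compiled code; the R layer prepares the sparse Hessian, the gate term
## and the exact excitation amplitude.
.langevin <- function(x, v, masses, potential, n_steps, dt, friction,
                      temperature, record_stride,
                      excite_steps = integer(0), direction = NULL,
                      delta_T = 0) {
  m3 <- rep(masses, each = 3)
  alpha <- 0
  if (length(excite_steps) && delta_T > 0) {
    if (is.null(direction) || sqrt(sum(direction^2)) == 0)
      stop("excitation direction is zero")
    e_target <- 1.5 * length(masses) * .kB * delta_T
    alpha <- sqrt(2 * e_target * .E_CONV / sum(m3 * direction^2))
  }
  gate <- if (!is.null(potential$gate))
    list(idx = as.integer(potential$gate$idx - 1L),
         ux = potential$gate$u[, 1], uy = potential$gate$u[, 2],
         tx = potential$gate$tang[, 1], ty = potential$gate$tang[, 2],
         z0 = potential$gate$z0, c = potential$gate$c, w = potential$gate$w,
         h = potential$gate$h, k_perp = potential$gate$k_perp)
  else list()
  out <- .baoab_cpp(x, v, m3, as.integer(potential$pi - 1L),
                    as.integer(potential$pj - 1L),
                    potential$u[, 1], potential$u[, 2], potential$u[, 3],
                    potential$k, potential$x0,
                    as.integer(n_steps), dt, friction, temperature,
                    as.integer(record_stride),
                    as.integer(excite_steps),
                    if (is.null(direction)) numeric(0) else direction,
                    alpha, gate)
  out
}

#' Run one MDeNM replica
#'
#' Langevin dynamics at the bath temperature with periodic kinetic-energy
#' injections along a fixed direction: one excitation at t = 0 and one
#' after each relaxation interval, `n_excitations` in total, the run ending
#' one relaxation interval after the last excitation.
#'
#' @param structure starting `channel_structure` (must carry masses or the
#'   110 amu default is used).
#' @param potential an `mdenm_potential`.
#' @param direction flat 3n excitation direction (unit norm).
#' @param config an [excitation_config()].
#' @param replica_id used to derive the replica's seed (`seed + replica_id`).
#' @return an object of class `replica_result`: trajectory (ensemble),
#'   `injected_energy` per excitation (kcal/mol), recorded kinetic
#'   temperatures, the direction and the seed used.
#' @export
run_replica <- function(structure, potential, direction, config,
                        replica_id = 0L) {
  stopifnot(inherits(config, "excitation_config"))
  if (length(direction) != 3L * n_atoms(structure))
    stop("direction length ", length(direction),
         " does not match 3 x ", n_atoms(structure), " atoms")
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) direction <- direction / nrm
  masses <- atom_masses(structure)
  n <- length(masses)
  seed <- config$seed + replica_id
  set.seed(seed)
  steps_per_period <- round(config$relaxation_time / config$timestep)
  n_steps <- steps_per_period * config$n_excitations
  excite_steps <- steps_per_period * (seq_len(config$n_excitations) - 1L)
  v0 <- maxwell_velocities(masses, config$bath_temperature)
  out <- .langevin(as_xyz(structure), v0, masses, potential, n_steps,
                   config$timestep, config$friction,
                   config$bath_temperature, config$record_stride,
                   excite_steps = excite_steps, direction = direction,
                   delta_T = config$delta_T)
  traj <- channel_ensemble(structure$atoms, out$frames,
                           source = sprintf("replica %d (seed %d)",
                                            replica_id, seed))
  base::structure(list(direction = direction,
                 trajectory = traj,
                 injected_energy = rep(1.5 * n * .kB * config$delta_T,
                                       config$n_excitations),
                 kinetic_temperature = out$temps,
                 potential_energy = out$energies,
                 steps = out$steps, seed = seed, replica_id = replica_id),
            class = "replica_result")
}

#' @export
print.replica_result <- function(x, ...) {
  cat("replica_result: replica", x$replica_id, "-",
      n_frames(x$trajectory), "frames,",
      length(x$injected_energy), "excitations of",
      signif(x$injected_energy[1], 4), "kcal/mol (seed", x$seed, ")\n")
  invisible(x)
}

#' Combine selected modes into uniformly spread excitation directions
#'
#' Samples coefficient vectors uniformly on the unit hypersphere of the
#' selected-mode subspace and keeps a candidate only if the structures
#' displaced along it to `probe_rmsd` stay at least a minimum RMSD away
#' from every previously accepted direction's displaced structure.  Since
#' the mode vectors are orthonormal, that pairwise displaced-structure RMSD
#' is `probe_rmsd` times the chord distance between coefficient vectors,
#' so the spacing rule acts directly on the hypersphere.  The floor is
#' `min_spacing_factor` times a covering-based estimate of the uniform
#' spacing, `2 (1/n)^{1/(m-1)}` chord units for `m` modes; opposite
#' directions count as distinct (they displace the structure differently).
#'
#' @param modes a `mode_set` with a selection (or any `mode_set`, all
#'   non-rigid modes then used).
#' @param n_replicas directions requested.
#' @param probe_rmsd Angstrom, displacement at which spacing is measured.
#' @param seed RNG seed.
#' @param min_spacing_factor fraction of the estimated uniform spacing
#'   enforced as the minimum.
#' @param max_tries rejection-sampling budget per requested direction.
#' @return 3n x n_replicas matrix of unit Cartesian directions, with
#'   attributes `coefficients` (m x n matrix), `min_rmsd_spacing` (the
#'   enforced floor in RMSD units).  Fewer than `n_replicas` columns are
#'   returned with a warning if the spacing rule cannot be met.
#' @export
combine_modes <- function(modes, n_replicas, probe_rmsd = 1, seed = 1L,
                          min_spacing_factor = 0.8, max_tries = 2000L) {
  idx <- if (!is.null(modes$selection)) selected_modes(modes)
         else which(!modes$zero)
  m <- length(idx)
  if (m < 1L) stop("no selected modes to combine")
  V <- vapply(idx, function(k) {
    v <- .mode_cartesian(modes, k)
    v / sqrt(sum(v^2))
  }, numeric(nrow(modes$vectors)))
  set.seed(seed)
  if (m == 1L) {
    if (n_replicas > 2L)
      warning("one mode admits only two distinct directions")
    n_keep <- min(n_replicas, 2L)
    coef <- matrix(c(1, -1)[seq_len(n_keep)], nrow = 1)
    dirs <- V %*% coef
    floor_chord <- 2
  } else {
    floor_chord <- min_spacing_factor * 2 * (1 / n_replicas)^(1 / (m - 1))
    coef <- matrix(NA_real_, m, 0)
    tries <- 0L
    while (ncol(coef) < n_replicas && tries < max_tries * n_replicas) {
      tries <- tries + 1L
      c0 <- stats::rnorm(m)
      c0 <- c0 / sqrt(sum(c0^2))
      ok <- ncol(coef) == 0L ||
        min(sqrt(colSums((coef - c0)^2))) >= floor_chord
      if (ok) coef <- cbind(coef, c0)
    }
    if (ncol(coef) < n_replicas)
      warning("placed only ", ncol(coef), " of ", n_replicas,
              " directions under the spacing rule")
    dirs <- V %*% coef
  }
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  attr(dirs, "coefficients") <- coef
  attr(dirs, "min_rmsd_spacing") <- probe_rmsd * floor_chord
  attr(dirs, "probe_rmsd") <- probe_rmsd
  dirs
}
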