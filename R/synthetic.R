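#' The five-state gating taxonomy
#'
#' Gating states are defined from the open/closed status of the two
#' principal constriction points (residues 124 and 132) plus the secondary
#' constriction at residue 129: fully open (all gates wide enough for an
#' unhydrated K+ ion), fully closed (both principal gates shut), the two
#' partially open combinations, and the state in which only the 129 level
#' obstructs an otherwise open pore.
#'
#' @return character vector of the five state names.
#' @export
gating_states <- function() {
  c("FULLY_OPEN", "FULLY_CLOSED",
    "PARTIAL_124_OPEN_132_CLOSED", "PARTIAL_132_OPEN_124_CLOSED",
    "GATE129_CLOSED")
}

## which gates are open in each state (124, 129, 132); the two PARTIAL
## states leave the secondary 129 level open and FULLY_CLOSED shuts it,
## so that each state maps to one unambiguous gate geometry
.state_gates <- function(state) {
  switch(state,
    FULLY_OPEN                  = c(`124` = TRUE,  `129` = TRUE,  `132` = TRUE),
    FULLY_CLOSED                = c(`124` = FALSE, `129` = FALSE, `132` = FALSE),
    PARTIAL_124_OPEN_132_CLOSED = c(`124` = TRUE,  `129` = TRUE,  `132` = FALSE),
    PARTIAL_132_OPEN_124_CLOSED = c(`124` = FALSE, `129` = TRUE,  `132` = TRUE),
    GATE129_CLOSED              = c(`124` = TRUE,  `129` = FALSE, `132` = TRUE),
    stop("unknown gating state: ", state))
}

#' Reference gating-state population mixes
#'
#' Frame-wise state fractions reported for relaxed KirBac3.1 ensembles:
#' the wild type occupies all four two-gate states (fully open 6.8%, fully
#' closed 50.2%, 124-open/132-closed 28.8%, 132-open/124-closed 14.2%) and
#' never the 129-closed state, whereas the S129R mutant is split between
#' fully open (52.8%) and 129-closed (47.2%) only.
#'
#' @param variant `"WT"` or `"S129R"`.
#' @return named numeric vector of fractions over [gating_states()],
#'   summing to 1.
#' @export
reference_populations <- function(variant = c("WT", "S129R")) {
  variant <- match.arg(variant)
  p <- if (variant == "WT")
    c(FULLY_OPEN = 6.8, FULLY_CLOSED = 50.2,
      PARTIAL_124_OPEN_132_CLOSED = 28.8,
      PARTIAL_132_OPEN_124_CLOSED = 14.2, GATE129_CLOSED = 0.0)
  else
    c(FULLY_OPEN = 52.8, FULLY_CLOSED = 0.0,
      PARTIAL_124_OPEN_132_CLOSED = 0.0,
      PARTIAL_132_OPEN_124_CLOSED = 0.0, GATE129_CLOSED = 47.2)
  p / sum(p)
}

#' Parameters of the synthetic channel generator
#'
#' Controls the idealized tetramer geometry and the statistical structure of
#' generated ensembles.  `gate_radius_open` / `gate_radius_closed` place the
#' constriction side-chain pseudo-atoms at that radial distance from the
#' pore (z) axis, so a gate's diametric atom-atom distance is twice its
#' radius: 8.0 A when open and 2.4 A when closed by default, straddling the
#' 3.5275 A ionic diameter with a margin far exceeding the coordinate noise.
#'
#' @param n_frames frames per generated ensemble.
#' @param state_probs named fractions over [gating_states()] (must sum
#'   to 1); default: the wild-type reference mix.
#' @param gate_radius_open,gate_radius_closed Angstrom.
#' @param coord_noise_sd isotropic per-atom Gaussian noise, Angstrom.
#' @param kink_angle_deg TM1 kink at residue 56; scalar or one value per
#'   chain A-D.
#' @param ctd_rotation_deg rotation of the cytoplasmic domain about the
#'   pore axis, degrees.
#' @param seed RNG seed (generation is fully reproducible).
#' @param mass pseudo-atom mass in amu (one residue per bead).
#' @return an object of class `synthetic_params`.
#' @export
synthetic_params <- function(n_frames = 100L,
                             state_probs = reference_populations("WT"),
                             gate_radius_open = 4.0,
                             gate_radius_closed = 1.2,
                             coord_noise_sd = 0.15,
                             kink_angle_deg = 13,
                             ctd_rotation_deg = 0,
                             seed = 1L,
                             mass = 110) {
  state_probs <- unlist(state_probs)
  if (abs(sum(state_probs) - 1) > 1e-9)
    stop("state_probs must sum to 1")
  if (!all(names(state_probs) %in% gating_states()))
    stop("unknown state in state_probs: ",
         paste(setdiff(names(state_probs), gating_states()), collapse = ", "))
  if (gate_radius_open <= 0 || gate_radius_closed <= 0)
    stop("gate radii must be positive")
  if (gate_radius_open <= gate_radius_closed)
    stop("gate_radius_open must exceed gate_radius_closed")
  if (coord_noise_sd < 0) stop("coord_noise_sd must be non-negative")
  if (!length(kink_angle_deg) %in% c(1L, 4L))
    stop("kink_angle_deg must be scalar or one value per chain")
  structure(list(n_frames = as.integer(n_frames), state_probs = state_probs,
                 gate_radius_open = gate_radius_open,
                 gate_radius_closed = gate_radius_closed,
                 coord_noise_sd = coord_noise_sd,
                 kink_angle_deg = kink_angle_deg,
                 ctd_rotation_deg = ctd_rotation_deg,
                 seed = as.integer(seed), mass = mass),
            class = "synthetic_params")
}

## check the separation margin between gate geometry and classification
## threshold: both gate settings must clear the ionic diameter by at least
## three noise standard deviations
.check_margins <- function(params, spec) {
  margin <- 3 * params$coord_noise_sd
  if (2 * params$gate_radius_open - spec$ionic_diameter < margin)
    stop("open-gate diametric distance ", 2 * params$gate_radius_open,
         " A does not exceed the ionic diameter by the 3-sigma noise margin")
  if (spec$ionic_diameter - 2 * params$gate_radius_closed < margin)
    stop("closed-gate diametric distance ", 2 * params$gate_radius_closed,
         " A is not below the ionic diameter by the 3-sigma noise margin")
  invisible(TRUE)
}

## landmark residue names; everything else is glycine
.landmark_resnames <- c(`35` = "HIS", `46` = "TRP", `56` = "LEU",
                        `80` = "ASP", `108` = "LEU", `121` = "MET",
                        `124` = "LEU", `129` = "ARG", `132` = "TYR",
                        `133` = "ALA", `138` = "PRO", `167` = "ARG",
                        `250` = "PHE", `266` = "ILE")

## deterministic low-discrepancy unit vectors, one per residue; used to
## corrugate the CA trace off its segment axes so that every atom has a
## generic 3D neighbourhood (a purely collinear/coplanar trace would give
## the elastic network spurious zero-frequency transverse modes)
.corrugation <- function(resno) {
  phi <- resno * 2.39996322972865332          # golden angle
  cz <- ((resno * 0.7548776662466927) %% 1) * 2 - 1
  sxy <- sqrt(pmax(0, 1 - cz^2))
  cbind(sxy * cos(phi), sxy * sin(phi), cz)
}

## CA trace of one chain in its own frame (chain azimuth 0 = +x), with a
## TM1 kink of `kink_deg` at residue 56.  Segments, inside-out:
## slide helix 35-45 near the membrane inner leaflet, TM1 ascending 46-80
## (two straight sub-segments meeting at 56), turret/pore helix 81-95,
## TM2 descending 96-120, bundle-crossing channel 121-133, CTD spiral
## 134-295.  TM1 is exactly straight (per sub-segment) so helix-axis fits
## are exact; every other segment is corrugated by 1 A.
.template_ca <- function(resno, kink_deg) {
  p <- matrix(NA_real_, length(resno), 3)
  th <- .deg2rad(kink_deg)
  u1 <- c(sin(th), 0, cos(th))       # 46 -> 56 direction (tilted)
  p56 <- c(13, 0, 3)
  for (k in seq_along(resno)) {
    i <- resno[k]
    p[k, ] <- if (i <= 45) {
      c(15 + (45 - i) * 1.5, 0, -12 - (45 - i) * 0.2)
    } else if (i <= 56) {
      p56 - (56 - i) * 1.5 * u1
    } else if (i <= 80) {
      p56 + (i - 56) * 1.5 * c(0, 0, 1)
    } else if (i <= 95) {
      t <- (i - 81) / 14
      (1 - t) * c(12, 0, 36) + t * c(5, 0, 12)
    } else if (i <= 120) {
      t <- (i - 96) / 24
      (1 - t) * c(5.5, 0, 11) + t * c(9.5, 0, -14)
    } else if (i <= 133) {
      c(9.5, 0, -15.5 - (i - 121) * 0.5)
    } else {
      az <- .deg2rad((i - 134) * 20)
      c(15 * cos(az), 15 * sin(az), -24 - (i - 134) * 28 / 161)
    }
  }
  wob <- !(resno >= 46 & resno <= 80)
  p[wob, ] <- p[wob, , drop = FALSE] + .corrugation(resno[wob])
  p
}

.build_chain <- function(chain_id, azimuth_deg, kink_deg, ctd_rotation_deg,
                         gate_radii, spec, mass) {
  resno_ca <- 35:295
  ca <- .template_ca(resno_ca, kink_deg)
  ## rotate the cytoplasmic domain (below the bundle crossing) about z
  ctd <- resno_ca >= 134
  if (ctd_rotation_deg != 0)
    ca[ctd, ] <- ca[ctd, , drop = FALSE] %*%
      t(rotation_about(c(0, 0, 1), ctd_rotation_deg))
  rows <- vector("list", length(resno_ca))
  for (k in seq_along(resno_ca)) {
    i <- resno_ca[k]
    nm <- .landmark_resnames[as.character(i)]
    if (is.na(nm)) nm <- "GLY"
    r <- data.frame(atom_name = "CA", element = "C", resno = i, resname = nm,
                    chain = chain_id, x = ca[k, 1], y = ca[k, 2], z = ca[k, 3],
                    mass = mass, stringsAsFactors = FALSE)
    if (i %in% spec$constriction_residues) {
      g <- gate_radii[[as.character(i)]]
      r <- rbind(r, data.frame(atom_name = "SC", element = "C", resno = i,
                               resname = nm, chain = chain_id,
                               x = g, y = 0, z = ca[k, 3], mass = mass,
                               stringsAsFactors = FALSE))
    }
    rows[[k]] <- r
  }
  a <- do.call(rbind, rows)
  R <- rotation_about(c(0, 0, 1), azimuth_deg)
  a[, c("x", "y", "z")] <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a
}

#' Generate one idealized tetrameric channel structure
#'
#' Builds a four-chain (A-D) pseudo-atom tetramer with its pore on the z
#' axis: one CA bead per residue 35-295 plus a side-chain bead at each
#' constriction residue, placed at the gate radius implied by `state`.
#' Chains sit at azimuths 0/90/180/270 degrees so that (A,C) and (B,D) are
#' diametrically opposed.  The TM1 trace (46-80) is built from two straight
#' sub-segments meeting at residue 56 with the requested kink, and the
#' cytoplasmic domain (residues 134-295) is rotated about z by
#' `ctd_rotation_deg`.
#'
#' @param params a [synthetic_params()] object.
#' @param spec a [channel_spec()].
#' @param state gating state determining which gates are open.
#' @return a `channel_structure` with generator metadata.
#' @export
make_channel <- function(params = synthetic_params(), spec = channel_spec(),
                         state = "FULLY_OPEN") {
  .check_margins(params, spec)
  open <- .state_gates(state)
  kink <- rep(params$kink_angle_deg, length.out = 4)
  gate_radii <- lapply(open, function(o)
    if (o) params$gate_radius_open else params$gate_radius_closed)
  names(gate_radii) <- names(open)
  ## any constriction residue outside the 124/129/132 trio defaults to open
  for (cr in setdiff(as.character(spec$constriction_residues),
                     names(gate_radii)))
    gate_radii[[cr]] <- params$gate_radius_open
  chains <- mapply(.build_chain, LETTERS[1:4], c(0, 90, 180, 270), kink,
                   MoreArgs = list(ctd_rotation_deg = params$ctd_rotation_deg,
                                   gate_radii = gate_radii, spec = spec,
                                   mass = params$mass),
                   SIMPLIFY = FALSE)
  channel_structure(do.call(rbind, chains),
                    metadata = list(generator = "make_channel",
                                    state = state,
                                    hydrogens = "absent",
                                    symmetric_topology = "true"))
}

#' Generate a labelled synthetic ensemble
#'
#' Draws `n_frames` gating states i.i.d. from `params$state_probs`, builds
#' the corresponding gate geometry for each frame and adds isotropic
#' Gaussian coordinate noise.  Output is bitwise reproducible for a fixed
#' seed, and the drawn states are recorded as ground-truth labels.
#'
#' @inheritParams make_channel
#' @return a labelled `channel_ensemble`.
#' @export
make_ensemble <- function(params = synthetic_params(), spec = channel_spec()) {
  .check_margins(params, spec)
  probs <- params$state_probs[params$state_probs > 0]
  set.seed(params$seed)
  labels <- sample(names(probs), params$n_frames, replace = TRUE,
                   prob = as.numeric(probs))
  base <- lapply(unique(labels), function(s)
    as_xyz(make_channel(params, spec, state = s)))
  names(base) <- unique(labels)
  xyz <- do.call(rbind, base)[match(labels, unique(labels)), , drop = FALSE]
  if (params$coord_noise_sd > 0)
    xyz <- xyz + stats::rnorm(length(xyz), sd = params$coord_noise_sd)
  topo <- make_channel(params, spec, state = labels[1])$atoms
  channel_ensemble(topo, xyz, labels = labels,
                   source = sprintf("make_ensemble(seed=%d)", params$seed))
}
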