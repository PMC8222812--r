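## atom indices of one residue on one chain
.residue_atoms <- function(atoms, resno, chain) {
  idx <- which(atoms$resno == resno & atoms$chain == chain)
  if (length(idx) == 0L)
    stop("residue ", resno, " of chain ", chain, " not found")
  idx
}

#' Shortest inter-residue atomic distance
#'
#' Minimum over all atom pairs of the Euclidean distance between two
#' residues.  All atoms present are used, including hydrogens when the
#' structure has them (the structure metadata records whether it does).
#'
#' @param structure a `channel_structure`.
#' @param res_a,res_b lists with elements `resno` and `chain`.
#' @return distance in Angstrom.
#' @export
shortest_distance <- function(structure, res_a, res_b) {
  a <- structure$atoms
  ia <- .residue_atoms(a, res_a$resno, res_a$chain)
  ib <- .residue_atoms(a, res_b$resno, res_b$chain)
  xa <- coords(structure)[ia, , drop = FALSE]
  xb <- coords(structure)[ib, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(0, min(d2)))
}

.gate_labels <- function(spec) {
  unlist(lapply(spec$constriction_residues, function(r)
    vapply(spec$gate_pairs, function(p)
      paste0("d", r, "_", p[1], p[2]), character(1))))
}

## column indices (into the flat xyz layout) of each atom's x coordinate
.xcol <- function(i) 3L * (i - 1L) + 1L

#' The six gate distances of one structure
#'
#' Shortest diametric inter-chain distances at each constriction residue:
#' with the default spec, residues 124, 129, 132 for chain pairs (A,C) and
#' (B,D).
#'
#' @param structure a `channel_structure`.
#' @param spec a [channel_spec()].
#' @return named numeric vector (e.g. `d124_AC`, `d124_BD`, ...).
#' @export
gate_distances <- function(structure, spec = channel_spec()) {
  out <- unlist(lapply(spec$constriction_residues, function(r)
    vapply(spec$gate_pairs, function(p)
      shortest_distance(structure, list(resno = r, chain = p[1]),
                        list(resno = r, chain = p[2])), numeric(1))))
  names(out) <- .gate_labels(spec)
  out
}

#' Gate distances for every frame of an ensemble
#'
#' Vectorized across frames: for each constriction residue and chain pair
#' the minimum over the (few) atom-pair distances is taken per frame.
#'
#' @param ensemble a `channel_ensemble`.
#' @param spec a [channel_spec()].
#' @return `n_frames x (residues x pairs)` numeric matrix with the same
#'   column names as [gate_distances()].
#' @export
ensemble_gate_distances <- function(ensemble, spec = channel_spec()) {
  topo <- ensemble$topology
  xyz <- ensemble$xyz
  cols <- lapply(spec$constriction_residues, function(r)
    lapply(spec$gate_pairs, function(p) {
      ia <- .residue_atoms(topo, r, p[1])
      ib <- .residue_atoms(topo, r, p[2])
      best <- NULL
      for (i in ia) for (j in ib) {
        ci <- .xcol(i); cj <- .xcol(j)
        d <- sqrt((xyz[, ci] - xyz[, cj])^2 +
                  (xyz[, ci + 1L] - xyz[, cj + 1L])^2 +
                  (xyz[, ci + 2L] - xyz[, cj + 2L])^2)
        best <- if (is.null(best)) d else pmin(best, d)
      }
      best
    }))
  out <- do.call(cbind, unlist(cols, recursive = FALSE))
  colnames(out) <- .gate_labels(spec)
  out
}

## open/closed per gate level from the two diametric pair distances;
## rule "min": open requires BOTH pair distances above the ionic diameter
## (strictly greater); rule "either": one suffices
.gate_open <- function(d_pairs, ionic_diameter, rule) {
  agg <- if (rule == "min") do.call(pmin, d_pairs) else do.call(pmax, d_pairs)
  agg > ionic_diameter
}

#' Classify gating state from gate distances
#'
#' A gate level is open when its shortest diametric inter-chain distance
#' strictly exceeds the ionic diameter of K+ (both chain pairs must clear
#' it under the default `"min"` rule).  The five-state decision: both main
#' gates (124, 132) open with the 129 level open is FULLY_OPEN; both main
#' gates open with 129 closed is GATE129_CLOSED; one main gate open gives
#' the corresponding PARTIAL state; both closed is FULLY_CLOSED.  With a
#' spec lacking a secondary gate, the 129 level is ignored and
#' GATE129_CLOSED never occurs.
#'
#' @param d a named vector from [gate_distances()] or a matrix from
#'   [ensemble_gate_distances()].
#' @param spec a [channel_spec()].
#' @param rule `"min"` (default: both diametric pairs must exceed the
#'   ionic diameter for a gate to count as open) or `"either"`.
#' @return a character vector of states (length = rows of `d`), with the
#'   open/closed status of each gate level in attribute `gate_open`.
#' @export
classify_state <- function(d, spec = channel_spec(), rule = c("min", "either")) {
  rule <- match.arg(rule)
  if (is.null(dim(d))) d <- matrix(d, nrow = 1, dimnames = list(NULL, names(d)))
  lab <- .gate_labels(spec)
  if (!all(lab %in% colnames(d)))
    stop("distance columns do not match the spec's gates")
  open <- sapply(spec$constriction_residues, function(r) {
    pair_cols <- lab[startsWith(lab, paste0("d", r, "_"))]
    .gate_open(lapply(pair_cols, function(cn) d[, cn]),
               spec$ionic_diameter, rule)
  })
  if (is.null(dim(open))) open <- matrix(open, nrow = 1)
  colnames(open) <- as.character(spec$constriction_residues)
  g124 <- open[, as.character(spec$main_gates[1])]
  g132 <- open[, as.character(spec$main_gates[2])]
  g129 <- if (is.null(spec$secondary_gate)) rep(TRUE, nrow(open))
          else open[, as.character(spec$secondary_gate)]
  state <- ifelse(g124 & g132,
                  ifelse(g129, "FULLY_OPEN", "GATE129_CLOSED"),
                  ifelse(g124, "PARTIAL_124_OPEN_132_CLOSED",
                         ifelse(g132, "PARTIAL_132_OPEN_124_CLOSED",
                                "FULLY_CLOSED")))
  attr(state, "gate_open") <- open
  state
}

#' Gating-state population table
#'
#' Percentage of frames in each of the five gating states, with the
#' open/closed status at the secondary (129) level also tallied separately.
#'
#' @param x a `channel_ensemble` (frames are classified), or a character
#'   vector of states.
#' @param spec a [channel_spec()]; used for classification when `x` is an
#'   ensemble.
#' @param use_labels when `x` is a labelled ensemble, tabulate the
#'   ground-truth labels instead of classifying.
#' @return object of class `population_table`: data frame `state`, `count`,
#'   `percentage` (summing to 100), with `n_frames` and provenance
#'   attributes.
#' @export
population_table <- function(x, spec = channel_spec(), use_labels = FALSE) {
  states <- if (is.character(x)) x
    else if (use_labels) {
      if (is.null(x$labels)) stop("ensemble carries no labels")
      x$labels
    } else classify_state(ensemble_gate_distances(x, spec), spec)
  if (length(states) == 0L) stop("no frames to tabulate")
  counts <- table(factor(states, levels = gating_states()))
  out <- data.frame(state = names(counts),
                    count = as.integer(counts),
                    percentage = 100 * as.numeric(counts) / length(states),
                    stringsAsFactors = FALSE)
  structure(out, class = c("population_table", "data.frame"),
            n_frames = length(states),
            hydrogens = if (inherits(x, "channel_ensemble"))
              "absent" else NA_character_)
}

#' @export
print.population_table <- function(x, ...) {
  cat("Populations (%) over", attr(x, "n_frames"), "frames\n")
  df <- data.frame(`Opening type` = x$state,
                   `%` = sprintf("%.1f", x$percentage),
                   n = x$count, check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

## resolve a pair specification into a list of (res_a, chain_a, res_b,
## chain_b, label) combinations
.series_pairs <- function(res_a, res_b, mode, chains) {
  if (is.null(res_b)) res_b <- res_a
  switch(mode,
    adjacent = {
      nxt <- c(chains[-1], chains[1])
      Map(function(c1, c2) list(res_a, c1, res_b, c2,
                                sprintf("%d%s-%d%s", res_a, c1, res_b, c2)),
          chains, nxt)
    },
    diametric = {
      half <- length(chains) / 2
      Map(function(c1, c2) list(res_a, c1, res_b, c2,
                                sprintf("%d%s-%d%s", res_a, c1, res_b, c2)),
          chains[seq_len(half)], chains[seq_len(half) + half])
    },
    same_chain = lapply(chains, function(c1)
      list(res_a, c1, res_b, c1,
           sprintf("%d%s-%d%s", res_a, c1, res_b, c1))),
    stop("unknown pair mode: ", mode))
}

#' Per-frame shortest-distance series between residue pairs
#'
#' Tracks the shortest inter-residue distance across an ensemble for a set
#' of residue pairs: diametric pairs (chain n with chain n+2), adjacent
#' pairs (chain n with chain n+1, cyclic), or same-chain pairs, e.g. the
#' 129(n)-129(n+1) adjacent distances, the 129-132 same-chain contact, or
#' the His35-Arg167 and Pro138-Phe250 stabilizing contacts.
#'
#' @param ensemble a `channel_ensemble`.
#' @param res_a first residue number.
#' @param res_b second residue number (default: same as `res_a`).
#' @param mode `"adjacent"`, `"diametric"` or `"same_chain"`.
#' @param chains chain order defining adjacency (default A, B, C, D).
#' @param bin_width histogram bin width, Angstrom.
#' @param density also return a Gaussian kernel density (bandwidth by
#'   Silverman's rule, `stats::bw.nrd0`)?
#' @return object of class `distance_series`: `$series` (long data frame
#'   frame/pair/distance), `$histogram` (`hist` object, plot-ready),
#'   optional `$density`, and the parameters used.
#' @export
distance_series <- function(ensemble, res_a, res_b = NULL,
                            mode = c("adjacent", "diametric", "same_chain"),
                            chains = c("A", "B", "C", "D"),
                            bin_width = 0.2, density = FALSE) {
  mode <- match.arg(mode)
  topo <- ensemble$topology
  xyz <- ensemble$xyz
  pairs <- .series_pairs(res_a, res_b, mode, chains)
  series <- lapply(pairs, function(p) {
    ia <- .residue_atoms(topo, p[[1]], p[[2]])
    ib <- .residue_atoms(topo, p[[3]], p[[4]])
    best <- NULL
    for (i in ia) for (j in ib) {
      ci <- .xcol(i); cj <- .xcol(j)
      d <- sqrt((xyz[, ci] - xyz[, cj])^2 +
                (xyz[, ci + 1L] - xyz[, cj + 1L])^2 +
                (xyz[, ci + 2L] - xyz[, cj + 2L])^2)
      best <- if (is.null(best)) d else pmin(best, d)
    }
    data.frame(frame = seq_len(nrow(xyz)), pair = p[[5]], distance = best)
  })
  df <- do.call(rbind, series)
  rng <- range(df$distance)
  breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                ceiling(rng[2] / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(df$distance, breaks = breaks, plot = FALSE)
  out <- list(series = df, histogram = h,
              density = if (density) stats::density(df$distance,
                                                    bw = "nrd0") else NULL,
              res_a = res_a, res_b = res_b %||% res_a, mode = mode,
              bin_width = bin_width)
  class(out) <- "distance_series"
  out
}

#' @export
print.distance_series <- function(x, ...) {
  cat("distance_series:", x$mode, "pairs", x$res_a, "-", x$res_b, ":",
      length(unique(x$series$pair)), "pair(s) x",
      max(x$series$frame), "frames; mean",
      sprintf("%.2f", mean(x$series$distance)), "A, sd",
      sprintf("%.2f", stats::sd(x$series$distance)), "A\n")
  invisible(x)
}

#' @export
plot.distance_series <- function(x, ...) {
  graphics::plot(x$histogram, freq = FALSE, col = "grey85", border = "white",
                 main = sprintf("Shortest distances %d-%d (%s)",
                                x$res_a, x$res_b, x$mode),
                 xlab = "distance (A)", ...)
  if (!is.null(x$density)) graphics::lines(x$density, lwd = 2)
  invisible(x)
}
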