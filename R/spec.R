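#' Channel analysis specification
#'
#' Bundles the geometric conventions of the gating analysis: the channel
#' (bundle-crossing) residue range, the constriction-point residues, which
#' chain pairs are diametrically opposed, and the ionic diameter used as the
#' open/closed criterion.  Defaults correspond to KirBac3.1: channel region
#' Met121-Ala133, constriction points Leu124 / (Ser or Arg)129 / Tyr132,
#' diametric pairs (A,C) and (B,D), and the unhydrated K+ diameter
#' 3.5275 Angstrom.
#'
#' The five-state classifier needs to know which constriction points are the
#' two principal gates (`main_gates`, default 124 and 132) and which is the
#' secondary gate whose closure defines the "gating 129 closed" state
#' (`secondary_gate`, default 129).  Setting `secondary_gate = NULL` gives a
#' two-gate, four-state classifier in which the 129 level is ignored.
#'
#' @param channel_range inclusive residue interval of the channel region.
#' @param constriction_residues residue numbers of the constriction points.
#' @param gate_pairs list of length-2 chain vectors, diametrically opposed.
#' @param ionic_diameter Angstrom; a gate is open when its shortest
#'   diametric inter-chain atomic distance strictly exceeds this.
#' @param main_gates the two principal constriction residues.
#' @param secondary_gate the secondary constriction residue, or `NULL`.
#' @return An object of class `channel_spec`.
#' @export
channel_spec <- function(channel_range = c(121L, 133L),
                         constriction_residues = c(124L, 129L, 132L),
                         gate_pairs = list(c("A", "C"), c("B", "D")),
                         ionic_diameter = 3.5275,
                         main_gates = c(124L, 132L),
                         secondary_gate = 129L) {
  gate_pairs <- lapply(gate_pairs, function(p) unlist(p, use.names = FALSE))
  stopifnot(length(channel_range) == 2, channel_range[1] <= channel_range[2])
  if (ionic_diameter <= 0) stop("ionic_diameter must be positive")
  if (!all(constriction_residues >= channel_range[1] &
           constriction_residues <= channel_range[2]))
    stop("constriction residues must lie inside channel_range")
  for (p in gate_pairs) {
    if (length(p) != 2L || p[1] == p[2])
      stop("each gate pair must name two distinct chains")
  }
  if (!all(main_gates %in% constriction_residues))
    stop("main_gates must be constriction residues")
  if (!is.null(secondary_gate) &&
      !secondary_gate %in% constriction_residues)
    stop("secondary_gate must be a constriction residue")
  structure(list(channel_range = as.integer(channel_range),
                 constriction_residues = as.integer(constriction_residues),
                 gate_pairs = gate_pairs,
                 ionic_diameter = ionic_diameter,
                 main_gates = as.integer(main_gates),
                 secondary_gate = if (is.null(secondary_gate)) NULL
                                  else as.integer(secondary_gate)),
            class = "channel_spec")
}

#' @export
print.channel_spec <- function(x, ...) {
  cat("channel_spec: channel", x$channel_range[1], "-", x$channel_range[2],
      "; constrictions", paste(x$constriction_residues, collapse = "/"),
      "; pairs", paste(vapply(x$gate_pairs, paste, "", collapse = "-"),
                       collapse = ","),
      "; ionic diameter", x$ionic_diameter, "A\n")
  invisible(x)
}
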