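#' Conformational ensembles
#'
#' A `channel_ensemble` is an ordered set of conformations sharing one
#' topology (identical atom count and ordering).  Coordinates are stored as
#' an `n_frames x 3*n_atoms` matrix in (x1, y1, z1, x2, ...) order; the
#' shared atom table is kept once.  Frames may carry optional ground-truth
#' gating-state labels (see [gating_states()]).
#'
#' @param topology atom table shared by all frames (as in
#'   [channel_structure()], without meaningful coordinates).
#' @param xyz `n_frames x 3*n_atoms` coordinate matrix (Angstrom).
#' @param labels optional character vector of per-frame gating states.
#' @param source free-form provenance string.
#' @return An object of class `channel_ensemble`.
#' @export
channel_ensemble <- function(topology, xyz, labels = NULL, source = "") {
  if (inherits(topology, "channel_structure")) topology <- topology$atoms
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * nrow(topology))
    stop("coordinate matrix has ", ncol(xyz), " columns; topology implies ",
         3L * nrow(topology))
  if (!is.null(labels) && length(labels) != nrow(xyz))
    stop("labels must have one entry per frame")
  structure(list(topology = topology, xyz = xyz, labels = labels,
                 source = source),
            class = "channel_ensemble")
}

#' @export
print.channel_ensemble <- function(x, ...) {
  cat("channel_ensemble:", n_frames(x), "frames x", n_atoms(x), "atoms")
  if (!is.null(x$labels)) cat(" (labelled)")
  if (nzchar(x$source)) cat("  source:", x$source)
  cat("\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param x a `channel_ensemble`.
#' @export
n_frames <- function(x) nrow(x$xyz)

#' Extract one frame as a structure
#' @param x a `channel_ensemble`.
#' @param i frame index (1-based).
#' @return a `channel_structure`.
#' @export
ensemble_frame <- function(x, i) {
  stopifnot(i >= 1, i <= n_frames(x))
  a <- x$topology
  a[, c("x", "y", "z")] <- matrix(x$xyz[i, ], ncol = 3, byrow = TRUE)
  channel_structure(a)
}

#' Build an ensemble from a list of structures
#' @param frames list of `channel_structure`s sharing one topology.
#' @param labels,source see [channel_ensemble()].
#' @export
as_ensemble <- function(frames, labels = NULL, source = "") {
  stopifnot(length(frames) >= 1)
  n <- vapply(frames, n_atoms, integer(1))
  if (length(unique(n)) != 1L)
    stop("frames differ in atom count: ", paste(unique(n), collapse = ", "))
  xyz <- do.call(rbind, lapply(frames, as_xyz))
  channel_ensemble(frames[[1]]$atoms, xyz, labels, source)
}

.element_from <- function(elesy, elety) {
  ele <- as.character(elesy)
  bad <- is.na(ele) | ele == ""
  ele[bad] <- substr(gsub("[^A-Za-z].*", "", elety[bad]), 1, 1)
  ele
}

.atoms_from_bio3d <- function(pdb, path) {
  a <- pdb$atom
  bad <- which(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))
  if (length(bad))
    stop("parse error in '", path, "': non-numeric coordinates for atom record(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  chain <- as.character(a$chain)
  chain[is.na(chain)] <- "A"
  data.frame(atom_name = as.character(a$elety),
             element = .element_from(a$elesy, a$elety),
             resno = as.integer(a$resno),
             resname = as.character(a$resid),
             chain = chain,
             x = a$x, y = a$y, z = a$z,
             stringsAsFactors = FALSE)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records into a [channel_structure()].  Coordinates are
#' in Angstrom, residue numbers are kept verbatim and hydrogens are retained
#' when present (the hydrogen provenance is recorded in the structure
#' metadata, since shortest-distance analyses depend on it).
#'
#' @param path path to a PDB file.
#' @return a `channel_structure` (first MODEL only; see [read_ensemble()]
#'   for multi-model files).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e)
                    stop("parse error in '", path, "': ", conditionMessage(e)))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop("no ATOM/HETATM records in '", path, "'")
  channel_structure(.atoms_from_bio3d(pdb, path),
                    metadata = list(source = path))
}

#' Write a structure or ensemble to PDB
#'
#' Ensembles are written as multi-model PDB (MODEL/ENDMDL).  Coordinates are
#' rounded to the 3 decimal places of the PDB fixed-width format.
#'
#' @param x a `channel_structure` or `channel_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "channel_structure")) {
    a <- x$atoms
    xyz <- matrix(as_xyz(x), nrow = 1)
  } else if (inherits(x, "channel_ensemble")) {
    a <- x$topology
    xyz <- x$xyz
  } else stop("cannot write object of class ", class(x)[1])
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   elety = a$atom_name, elesy = a$element)
  invisible(path)
}

#' Read an ensemble from one multi-model PDB or several single files
#'
#' All frames must share one topology (atom count, names, residue numbering
#' and chains); a mismatch is an error.  Optional per-frame gating labels can
#' be read from a CSV with columns `frame_index`, `state`.
#'
#' @param paths one multi-model PDB path, or a vector of single-model paths
#'   (frames taken in the given order).
#' @param labels_path optional labels CSV.
#' @return a `channel_ensemble`.
#' @export
read_ensemble <- function(paths, labels_path = NULL) {
  stopifnot(length(paths) >= 1)
  if (length(paths) == 1L) {
    pdb <- tryCatch(suppressWarnings(
      bio3d::read.pdb(paths, multi = TRUE, verbose = FALSE)),
      error = function(e) stop("parse error in '", paths, "': ",
                               conditionMessage(e)))
    topo <- .atoms_from_bio3d(pdb, paths)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    ens <- channel_ensemble(topo, unclass(xyz)[, , drop = FALSE],
                            source = paths)
  } else {
    frames <- lapply(paths, read_pdb)
    nat <- vapply(frames, n_atoms, integer(1))
    if (length(unique(nat)) != 1L)
      stop("topology error: frames differ in atom count (",
           paste(unique(nat), collapse = " vs "), ")")
    ref <- frames[[1]]$atoms
    for (k in seq_along(frames)[-1]) {
      a <- frames[[k]]$atoms
      if (!identical(a$atom_name, ref$atom_name) ||
          !identical(a$resno, ref$resno) || !identical(a$chain, ref$chain))
        stop("topology error: frame ", k, " does not match frame 1")
    }
    ens <- as_ensemble(frames, source = paste(paths[1], "..."))
  }
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    if (!all(c("frame_index", "state") %in% names(lab)))
      stop("labels CSV needs columns frame_index, state")
    lab <- lab[order(lab$frame_index), ]
    if (nrow(lab) != n_frames(ens))
      stop("labels CSV has ", nrow(lab), " rows for ", n_frames(ens), " frames")
    ens$labels <- lab$state
  }
  ens
}

#' Write an ensemble plus its gating labels
#' @param x a labelled `channel_ensemble`.
#' @param path multi-model PDB output path.
#' @param labels_path optional CSV output (`frame_index`, `state`).
#' @export
write_ensemble <- function(x, path, labels_path = NULL) {
  write_pdb(x, path)
  if (!is.null(labels_path)) {
    if (is.null(x$labels)) stop("ensemble carries no labels")
    utils::write.csv(data.frame(frame_index = seq_len(n_frames(x)),
                                state = x$labels),
                     labels_path, row.names = FALSE)
  }
  invisible(path)
}
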