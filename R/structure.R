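#' Channel structure objects
#'
#' A `channel_structure` holds one conformation of a (possibly tetrameric)
#' protein as a flat atom table: atom name, element, residue number and name,
#' chain identifier and Cartesian coordinates in Angstrom.  Residue numbers
#' are taken verbatim from the source (1-based PDB numbering); no renumbering
#' is ever performed, so literature residue identities (Leu124, Tyr132, ...)
#' can be addressed directly.
#'
#' @param atoms data frame with columns `atom_name`, `element`, `resno`,
#'   `resname`, `chain`, `x`, `y`, `z` and optionally `mass` (amu).
#' @param metadata named list of free-form strings (e.g. hydrogen
#'   provenance, generator parameters).
#' @return An object of class `channel_structure`.
#' @export
channel_structure <- function(atoms, metadata = list()) {
  required <- c("atom_name", "element", "resno", "resname", "chain",
                "x", "y", "z")
  miss <- setdiff(required, names(atoms))
  if (length(miss))
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("structure must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must all be finite")
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  if (is.null(metadata$hydrogens))
    metadata$hydrogens <- if (any(atoms$element == "H")) "present" else "absent"
  structure(list(atoms = atoms, metadata = metadata),
            class = "channel_structure")
}

#' @export
print.channel_structure <- function(x, ...) {
  a <- x$atoms
  cat("channel_structure:", nrow(a), "atoms,",
      length(unique(a$chain)), "chain(s) [",
      paste(sort(unique(a$chain)), collapse = ","), "], residues",
      min(a$resno), "-", max(a$resno), "\n")
  cat("  hydrogens:", x$metadata$hydrogens %||% "unknown", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of atoms in a structure or ensemble
#' @param x a `channel_structure` or `channel_ensemble`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) UseMethod("n_atoms")

#' @export
n_atoms.channel_structure <- function(x) nrow(x$atoms)

#' @export
n_atoms.channel_ensemble <- function(x) nrow(x$topology)

#' Coordinates of a structure as an n x 3 matrix
#' @param x a `channel_structure`.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(x) as.matrix(x$atoms[, c("x", "y", "z")])

#' Replace coordinates
#' @param x a `channel_structure`.
#' @param value an n x 3 matrix or flat length-3n vector (x1,y1,z1,...).
#' @export
`coords<-` <- function(x, value) {
  if (is.null(dim(value))) value <- matrix(value, ncol = 3, byrow = TRUE)
  stopifnot(nrow(value) == n_atoms(x))
  x$atoms[, c("x", "y", "z")] <- value
  x
}

## flat coordinate vector in (x1,y1,z1,x2,...) order, the layout shared
## with mode vectors, Hessians and the dynamics engine
as_xyz <- function(x) as.numeric(t(coords(x)))

atom_masses <- function(x, default = 110) {
  a <- if (inherits(x, "channel_ensemble")) x$topology else x$atoms
  if (!is.null(a$mass)) a$mass else rep(default, nrow(a))
}

#' Select a subset of atoms
#'
#' Subset by chain, residue interval and/or element, preserving atom order.
#'
#' @param x a `channel_structure`.
#' @param chain optional chain id (or vector of ids).
#' @param residues optional inclusive residue interval `c(lo, hi)` or an
#'   explicit vector of residue numbers.
#' @param heavy_only drop hydrogens (element `"H"`)?
#' @param atom_names optional atom-name filter (e.g. `"CA"`).
#' @return the subset as a `channel_structure`; empty selections are an error.
#' @export
select_atoms <- function(x, chain = NULL, residues = NULL,
                         heavy_only = FALSE, atom_names = NULL) {
  stopifnot(inherits(x, "channel_structure"))
  keep <- rep(TRUE, n_atoms(x))
  a <- x$atoms
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(residues)) {
    res <- if (length(residues) == 2L) seq(residues[1], residues[2]) else residues
    keep <- keep & a$resno %in% res
  }
  if (heavy_only) keep <- keep & a$element != "H"
  if (!is.null(atom_names)) keep <- keep & a$atom_name %in% atom_names
  if (!any(keep)) stop("selection is empty")
  channel_structure(a[keep, , drop = FALSE], x$metadata)
}

#' Assemble a C4 tetramer from a monomer
#'
#' Places four copies of a single-chain structure related by successive 90
#' degree rotations about `axis` (through the origin), naming the chains
#' A, B, C, D.  This idealized four-fold assembly stands in for
#' crystallographic symmetry expansion; atom order is preserved within each
#' chain.
#'
#' @param monomer a single-chain `channel_structure`.
#' @param axis rotation axis (3-vector, need not be normalized).
#' @return a four-chain `channel_structure`.
#' @export
assemble_c4 <- function(monomer, axis = c(0, 0, 1)) {
  stopifnot(inherits(monomer, "channel_structure"))
  if (length(unique(monomer$atoms$chain)) != 1L)
    stop("assemble_c4 expects a single-chain monomer")
  xyz <- coords(monomer)
  out <- vector("list", 4)
  for (k in 0:3) {
    R <- rotation_about(axis, 90 * k)
    a <- monomer$atoms
    a$chain <- LETTERS[k + 1]
    a[, c("x", "y", "z")] <- xyz %*% t(R)
    out[[k + 1]] <- a
  }
  channel_structure(do.call(rbind, out), monomer$metadata)
}

#' Apply a rigid-body transform to a structure
#' @param x a `channel_structure`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 shift (Angstrom).
#' @return the transformed structure.
#' @export
transform_structure <- function(x, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- coords(x) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  coords(x) <- xyz
  x
}
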