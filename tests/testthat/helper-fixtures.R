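## Shared fixtures, all built in code.

## cache the default synthetic channel: many tests only read it
default_channel <- local({
  cache <- NULL
  function(state = "FULLY_OPEN") {
    key <- state
    if (is.null(cache[[key]]))
      cache[[key]] <<- make_channel(state = state)
    cache[[key]]
  }
})

## minimal hand-built structure: arbitrary atoms at given coordinates
atoms_at <- function(xyz, resno = seq_len(nrow(xyz)), chain = "A",
                     atom_name = "CA", element = "C",
                     resname = "GLY", mass = 110) {
  channel_structure(data.frame(
    atom_name = rep(atom_name, length.out = nrow(xyz)),
    element = rep(element, length.out = nrow(xyz)),
    resno = rep(resno, length.out = nrow(xyz)),
    resname = rep(resname, length.out = nrow(xyz)),
    chain = rep(chain, length.out = nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    mass = mass, stringsAsFactors = FALSE))
}

## two atoms separated by d along x
two_atom_structure <- function(d = 3) {
  atoms_at(rbind(c(0, 0, 0), c(d, 0, 0)), resno = 1:2)
}

## a small 3D blob with generic geometry (connected, rigid network)
blob_structure <- function(n = 30, seed = 42, scale = 3) {
  set.seed(seed)
  atoms_at(matrix(stats::rnorm(3 * n, sd = scale), ncol = 3),
           resno = seq_len(n))
}

## a compact sub-channel used for cheap dynamics tests
small_channel <- function(state = "FULLY_OPEN") {
  select_atoms(default_channel(state), residues = c(100, 150))
}

## hand-planted mode set on the default channel: a rigid z-rotation, an
## elliptical channel mode, a radial breathing mode localized on the
## channel region, and a generic mode, orthonormalized in that order with
## ascending placeholder eigenvalues.
planted_mode_set <- function(structure, spec = channel_spec()) {
  a <- structure$atoms
  n <- nrow(a)
  xyz <- coords(structure)
  region <- a$resno >= spec$channel_range[1] & a$resno <= spec$channel_range[2]
  radial <- function(sel, weight = rep(1, sum(sel))) {
    v <- matrix(0, n, 3)
    p <- xyz[sel, 1:2, drop = FALSE]
    u <- p / sqrt(rowSums(p^2))
    v[sel, 1:2] <- u * weight
    as.numeric(t(v))
  }
  ## rigid rotation about z: v = z x r
  vrot <- as.numeric(t(cbind(-xyz[, 2], xyz[, 1], 0)))
  ## spherical breathing: all channel-region atoms radially outward
  vbreath <- radial(region)
  ## elliptical: A,C outward, B,D inward on the channel region, with the
  ## probe residue damped so the breathing mode has the strictly larger
  ## probe-residue variation after normalization
  wts <- ifelse(a$chain[region] %in% c("A", "C"), 1, -1) *
    ifelse(a$resno[region] == 125, 0.5, 1)
  vellip <- radial(region, wts)
  set.seed(11)
  vrand <- stats::rnorm(3 * n)
  V <- cbind(vrot, vellip, vbreath, vrand)
  ## Gram-Schmidt
  for (k in seq_len(ncol(V))) {
    if (k > 1)
      V[, k] <- V[, k] - V[, 1:(k - 1), drop = FALSE] %*%
        crossprod(V[, 1:(k - 1), drop = FALSE], V[, k])
    V[, k] <- V[, k] / sqrt(sum(V[, k]^2))
  }
  base::structure(list(vectors = V, values = c(0.5, 1, 2, 3),
                       frequencies = sqrt(c(0.5, 1, 2, 3)),
                       zero = rep(FALSE, 4), mass_weighted = FALSE,
                       masses = NULL, selection = NULL),
                  class = "mode_set")
}

expect_deg_equal <- function(a, b, tol = 1e-6) {
  d <- abs(((a - b + 180) %% 360) - 180)
  expect_lt(max(d), tol)
}
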