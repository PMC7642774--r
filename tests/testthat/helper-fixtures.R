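# Shared fixture builders. Everything here is independent of the package
# internals it is used to check: rotations come from an axis-angle formula,
# PDB text is written literally, and expected values are computed with plain
# arithmetic.

# Minimal 3-residue (ALA, GLY, SER) PDB block with CA/CB/O (no CB for GLY).
toy_pdb_lines <- function(b = 10.0, chain = "A") {
  fmt <- function(serial, elety, resid, resno, x, y, z, elesy) {
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00%6.2f           %s",
            serial, elety, resid, chain, resno, x, y, z, b, elesy)
  }
  c(fmt(1, "CA", "ALA", 1, 0.0, 0.0, 0.0, "C"),
    fmt(2, "CB", "ALA", 1, 1.5, 0.0, 0.0, "C"),
    fmt(3, "O",  "ALA", 1, 0.0, 1.2, 0.0, "O"),
    fmt(4, "CA", "GLY", 2, 3.8, 0.0, 0.0, "C"),
    fmt(5, "O",  "GLY", 2, 3.8, 1.2, 0.0, "O"),
    fmt(6, "CA", "SER", 3, 7.6, 0.0, 0.0, "C"),
    fmt(7, "CB", "SER", 3, 9.1, 0.0, 0.0, "C"),
    fmt(8, "O",  "SER", 3, 7.6, 1.2, 0.0, "O"),
    "END")
}

write_toy_pdb <- function(lines = toy_pdb_lines()) {
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  tf
}

# Rotation matrix about a given axis by angle (radians) — Rodrigues formula,
# written out so it does not depend on any package code.
axis_rotation <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rigid <- function() {
  R <- axis_rotation(rnorm(3), runif(1, 0, 2 * pi))
  list(R = R, t = rnorm(3, sd = 10))
}

# Apply a rigid motion to every atom of a CoarseModel.
transform_model <- function(m, R, tr) {
  mv <- function(x) sweep(x %*% t(R), 2, tr, "+")
  CoarseModel(resno = residueIndices(m), resid = residueNames(m),
              ca = mv(caCoords(m)), cb = mv(cbCoords(m)), o = mv(oCoords(m)),
              bfac = bFactors(m), chain = chainID(m))
}

# Planted block-structured Q matrix: within-cluster mean mu_w, between
# mu_b, i.i.d. Gaussian jitter, symmetrised, unit diagonal, clipped to (0,1].
band_matrix <- function(sizes, mu_w, mu_b, noise = 0.02) {
  lab <- rep(seq_along(sizes), sizes)
  n <- length(lab)
  q <- matrix(mu_b, n, n)
  q[outer(lab, lab, "==")] <- mu_w
  q <- q + matrix(rnorm(n * n, sd = noise), n, n)
  q <- (q + t(q)) / 2
  q <- pmin(pmax(q, 1e-6), 1)
  diag(q) <- 1
  list(q = q, labels = lab)
}

# CoarseModel straight from a Calpha matrix (no CB/O) — for metric toys.
ca_model <- function(ca, resno = seq_len(nrow(ca))) {
  CoarseModel(resno = resno, resid = rep("GLY", nrow(ca)), ca = ca)
}
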