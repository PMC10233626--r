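# Shared fixtures, built in code.

# minimal one-residue PDB text (ALA with a complete backbone)
write_minimal_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "END"), path)
  path
}

# synthetic chain of n ideal beta residues as a struct_tbl
ideal_chain <- function(n, chain = "A", start = 1L) {
  build_ideal_strand(n, chain = chain, start = start)
}

# hand-rolled mmCIF atom_site serialization of a struct_tbl (independent
# of the package's PDB writer)
write_minimal_cif <- function(st, path) {
  hdr <- c(
    "data_synthetic",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f 0.00 ? %d %s %s %s 1",
    seq_len(nrow(st)), st$element, st$elety, st$resname, st$chain,
    st$resno, st$x, st$y, st$z, st$occupancy, st$resno, st$resname,
    st$chain, st$elety)
  writeLines(c(hdr, rows, "#"), path)
  path
}

# random rigid transform (rotation + translation), seeded by caller
random_rigid <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)),
    3, 3, byrow = TRUE)
  list(R = R, t = rnorm(3, 0, 10))
}

transform_structure <- function(st, R, t) {
  xyz <- as.matrix(st[, c("x", "y", "z")]) %*% t(R)
  st$x <- xyz[, 1] + t[1]; st$y <- xyz[, 2] + t[2]; st$z <- xyz[, 3] + t[3]
  st
}

# brute-force hierarchical rotation-grid superposition oracle:
# global Euler-angle grid followed by nested local refinements around the
# best cell; translation is optimal analytically for each rotation.
grid_rmsd_oracle <- function(P, Q, coarse = 20, levels = 6) {
  rot <- function(a, b, c) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cc <- cos(c); sc <- sin(c)
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cc, -sc, 0, sc, cc, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  eval_r <- function(R) sqrt(mean(rowSums((P0 %*% t(R) - Q0)^2)))
  best <- c(0, 0, 0); best_v <- eval_r(rot(0, 0, 0))
  step <- coarse * pi / 180
  grid <- function(center, step, nsteps) {
    for (a in center[1] + step * (-nsteps:nsteps))
      for (b in center[2] + step * (-nsteps:nsteps))
        for (c in center[3] + step * (-nsteps:nsteps)) {
          v <- eval_r(rot(a, b, c))
          if (v < best_v) { best_v <<- v; best <<- c(a, b, c) }
        }
  }
  grid(c(pi, pi / 2, pi), step, ceiling(pi / step))  # full sphere
  for (l in seq_len(levels)) {
    step <- step / 4
    grid(best, step, 4)
  }
  best_v
}
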