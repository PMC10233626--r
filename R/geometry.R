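# Internal 3D geometry helpers: cross products, dihedrals, and NeRF-style
# placement of atoms from internal coordinates. All lengths in Angstrom,
# all angles in degrees.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

unit3 <- function(v) v / vnorm(v)

# Dihedral angle p1-p2-p3-p4 in degrees, in (-180, 180].
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit3(b2))
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Place atom D bonded to c with |c-D| = r, angle(b, c, D) = theta and
# dihedral(a, b, c, D) = chi (natural extension reference frame).
place_atom <- function(a, b, c, r, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-r * cos(th), r * sin(th) * cos(ch), r * sin(th) * sin(ch))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Standard backbone internal coordinates (Engh & Huber-like values).
BB_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

# Build an N/CA/C/O backbone from per-residue phi/psi/omega (degrees).
# phi[1] is unused (no preceding carbonyl); psi of the last residue only
# orients its carbonyl oxygen. Returns a list of n x 3 matrices.
build_backbone_matrices <- function(phi, psi, omega = NULL) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  if (is.null(omega)) omega <- rep(180, n)
  g <- BB_GEOM
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (k in seq_len(n)[-1]) {
    N[k, ]  <- place_atom(N[k - 1, ], CA[k - 1, ], C[k - 1, ], g$b_c_n,  g$a_ca_c_n, psi[k - 1])
    CA[k, ] <- place_atom(CA[k - 1, ], C[k - 1, ], N[k, ],     g$b_n_ca, g$a_c_n_ca, omega[k - 1])
    C[k, ]  <- place_atom(C[k - 1, ], N[k, ],      CA[k, ],    g$b_ca_c, g$a_n_ca_c, phi[k])
  }
  for (k in seq_len(n)) {
    psi_k <- if (k < n) psi[k] else 180
    O[k, ] <- place_atom(N[k, ], CA[k, ], C[k, ], g$b_c_o, g$a_ca_c_o, psi_k + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

# Measure backbone (phi, psi) from coordinate matrices; ends are NA.
measure_phipsi <- function(bb) {
  n <- nrow(bb$N)
  phi <- rep(NA_real_, n); psi <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    if (k > 1) phi[k] <- dihedral_angle(bb$C[k - 1, ], bb$N[k, ], bb$CA[k, ], bb$C[k, ])
    if (k < n) psi[k] <- dihedral_angle(bb$N[k, ], bb$CA[k, ], bb$C[k, ], bb$N[k + 1, ])
  }
  list(phi = phi, psi = psi)
}
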