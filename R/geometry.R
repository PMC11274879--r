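# Internal vector geometry: angles, dihedrals, and internal-coordinate
# chain construction (natural extension reference frame).

.vnorm <- function(v) sqrt(sum(v * v))

.vangle <- function(a, b, c) {
  # angle at b, degrees
  u <- a - b; w <- c - b
  acos(max(-1, min(1, sum(u * w) / (.vnorm(u) * .vnorm(w))))) * 180 / pi
}

.vdihedral <- function(p1, p2, p3, p4) {
  # signed dihedral p1-p2-p3-p4, degrees, IUPAC sign convention
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / .vnorm(b2)
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Place atom D given A, B, C with bond |C-D|, angle B-C-D and torsion
# A-B-C-D (degrees).
.place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180  # sign matches .vdihedral on the result
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- c - b; bc <- bc / .vnorm(bc)
  ab <- b - a
  nv <- c(ab[2] * bc[3] - ab[3] * bc[2],
          ab[3] * bc[1] - ab[1] * bc[3],
          ab[1] * bc[2] - ab[2] * bc[1])
  nv <- nv / .vnorm(nv)
  mv <- c(nv[2] * bc[3] - nv[3] * bc[2],
          nv[3] * bc[1] - nv[1] * bc[3],
          nv[1] * bc[2] - nv[2] * bc[1])
  c + d_local[1] * bc + d_local[2] * mv + d_local[3] * nv
}

# CB placement torsion (CB-CA-N-C' improper) solved once so that the
# C'-CA-CB angle matches the constants table.
.cb_torsion <- function(cc = ff_constants()) {
  bl <- cc$bond_lengths; an <- cc$bond_angles_deg
  n <- c(0, 0, 0)
  ca <- c(bl[["n_ca"]], 0, 0)
  cp <- .place_atom(c(-1, 0.7, 0), n, ca, bl[["ca_c"]], an[["n_ca_c"]], 0)
  f <- function(t) {
    cb <- .place_atom(cp, n, ca, bl[["ca_cb"]], an[["n_ca_cb"]], t)
    .vangle(cp, ca, cb) - an[["c_ca_cb"]]
  }
  stats::uniroot(f, c(95, 175), tol = 1e-10)$root
}

# Build four-bead chain coordinates from backbone dihedrals.
# phi[i]: C'(i-1)-N(i)-CA(i)-C'(i); psi[i]: N(i)-CA(i)-C'(i)-N(i+1);
# omega fixed at 180 (trans).  Returns a matrix with one row per bead in
# build_topology() order.  Used by the lattice initialiser and the
# synthetic secondary-structure generator.
.build_chain <- function(sequence, phi, psi, cc = ff_constants()) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(aa)
  stopifnot(length(phi) == L, length(psi) == L)
  bl <- cc$bond_lengths; an <- cc$bond_angles_deg
  tcb <- .cb_torsion(cc)

  Np <- matrix(0, L, 3); CAp <- matrix(0, L, 3); Cp <- matrix(0, L, 3)
  CBp <- matrix(NA_real_, L, 3)
  # first residue seeded in the xy-plane via a virtual previous C'
  Np[1L, ] <- c(0, 0, 0)
  CAp[1L, ] <- c(bl[["n_ca"]], 0, 0)
  virt <- c(-1.33, 0.5, 0)
  Cp[1L, ] <- .place_atom(virt, Np[1L, ], CAp[1L, ], bl[["ca_c"]],
                          an[["n_ca_c"]], phi[1L])
  for (i in seq_len(L)) {
    if (i > 1L) {
      Np[i, ] <- .place_atom(Np[i - 1L, ], CAp[i - 1L, ], Cp[i - 1L, ],
                             bl[["c_n"]], an[["ca_c_n"]], psi[i - 1L])
      CAp[i, ] <- .place_atom(CAp[i - 1L, ], Cp[i - 1L, ], Np[i, ],
                              bl[["n_ca"]], an[["c_n_ca"]], 180)
      Cp[i, ] <- .place_atom(Cp[i - 1L, ], Np[i, ], CAp[i, ],
                             bl[["ca_c"]], an[["n_ca_c"]], phi[i])
    }
    if (aa[i] != "G") {
      CBp[i, ] <- .place_atom(Cp[i, ], Np[i, ], CAp[i, ],
                              bl[["ca_cb"]], an[["n_ca_cb"]], tcb)
    }
  }
  out <- matrix(NA_real_, 0, 3)
  for (i in seq_len(L)) {
    rows <- rbind(Np[i, ], CAp[i, ], Cp[i, ])
    if (aa[i] != "G") rows <- rbind(rows, CBp[i, ])
    out <- rbind(out, rows)
  }
  dimnames(out) <- NULL
  out
}

# Minimum-image displacement (componentwise) for a periodic cubic box.
.min_image <- function(d, box) {
  d - box * round(d / box)
}

# Random rigid motion applied to an n x 3 coordinate matrix (for
# invariance tests and fixture placement).
.random_rotation <- function() {
  repeat {
    q <- stats::rnorm(4)
    nq <- .vnorm(q)
    if (nq > 1e-8) { q <- q / nq; break }
  }
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
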