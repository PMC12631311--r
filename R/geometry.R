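# Internal vector geometry and ideal-backbone construction.
# All coordinates are in Angstrom, all angles in degrees unless noted.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vec_angle <- function(a, b) {
  ct <- sum(a * b) / (vnorm(a) * vnorm(b))
  acos(max(-1, min(1, ct))) * 180 / pi
}

#' Dihedral angle of four points
#'
#' Signed torsion angle (degrees, in (-180, 180]) defined by the four
#' points p1-p2-p3-p4, using the IUPAC sign convention.
#'
#' @param p1,p2,p3,p4 Numeric xyz vectors (Angstrom).
#' @return Angle in degrees.
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# NeRF atom placement: position D from A-B-C with internal coordinates
# |CD| = bond, angle(B,C,D) = angle, torsion(A,B,C,D) = torsion.
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- -torsion * pi / 180   # sign so that dihedral(a,b,c,d) == torsion
  bc <- unitv(c - b)
  n <- unitv(vcross(b - a, bc))
  m <- vcross(n, bc)
  d <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + d[1L] * bc + d[2L] * m + d[3L] * n
}

# Ideal peptide internal coordinates (Engh-Huber-like averages).
.bb_geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, ca_cb = 1.521,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.5, ang_n_ca_cb = 110.5
)

# Tetrahedral C-beta from backbone N, CA, C. L-amino-acid chirality:
# CB lies on the positive side of unit(CA->N) x unit(CA->C).
synthesize_cb <- function(n, ca, c, length = .bb_geom$ca_cb) {
  a <- unitv(n - ca)
  b <- unitv(c - ca)
  ct <- sum(a * b)
  alpha <- cos(.bb_geom$ang_n_ca_cb * pi / 180) / (1 + ct)
  beta2 <- 1 - alpha^2 * (2 + 2 * ct)
  beta <- sqrt(max(beta2, 0))
  nrm <- unitv(vcross(a, b))
  ca + length * (alpha * (a + b) + beta * nrm)
}

#' Build an ideal polypeptide backbone from torsion angles
#'
#' Constructs N, CA, C, O (and CB) coordinates for a chain with the
#' given phi/psi torsions and ideal bond lengths/angles, using
#' sequential natural-extension (NeRF) placement. Used to build
#' reference conformations (ideal helices, strands, coil draws) for
#' tests and synthetic trajectories.
#'
#' @param n_res Number of residues.
#' @param phi,psi Backbone torsions in degrees; recycled to `n_res`.
#'   `phi[1]` is unused (no preceding carbonyl).
#' @param omega Peptide-bond torsion, default 180 (trans).
#' @param resno Author residue numbers (default `1:n_res`).
#' @param resid Three-letter residue names, recycled (default "ALA").
#' @param cb Logical; synthesize C-beta atoms (default TRUE).
#' @param chain Chain identifier.
#' @return A [structure3d] object.
#' @export
#' @examples
#' helix <- build_backbone(8, phi = -57, psi = -47)
build_backbone <- function(n_res, phi, psi, omega = 180,
                           resno = seq_len(n_res), resid = "ALA",
                           cb = TRUE, chain = "A") {
  stopifnot(n_res >= 1, length(resno) == n_res)
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  omega <- rep_len(omega, n_res)
  resid <- rep_len(toupper(resid), n_res)
  g <- .bb_geom

  N <- CA <- C <- O <- matrix(NA_real_, n_res, 3L)
  N[1L, ] <- c(0, 0, 0)
  CA[1L, ] <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  C[1L, ] <- CA[1L, ] + g$ca_c * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      # torsion CA(i-1)-C(i-1)-N(i)-CA(i) = omega
      CA[i, ] <- place_atom(CA[i - 1L, ], C[i - 1L, ], N[i, ],
                            g$n_ca, g$ang_c_n_ca, omega[i - 1L])
      C[i, ] <- place_atom(C[i - 1L, ], N[i, ], CA[i, ],
                           g$ca_c, g$ang_n_ca_c, phi[i])
    }
    if (i < n_res) {
      N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                                g$c_n, g$ang_ca_c_n, psi[i])
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                           g$c_o, g$ang_ca_c_o, psi[i] + 180)
    } else {
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                           g$c_o, g$ang_ca_c_o, psi[i] + 180)
    }
  }

  names_per_res <- if (cb) c("N", "CA", "CB", "C", "O") else c("N", "CA", "C", "O")
  nat <- length(names_per_res)
  atoms <- data.frame(
    name = rep(names_per_res, n_res),
    element = rep(substr(names_per_res, 1L, 1L), n_res),
    resno = rep(resno, each = nat),
    resid = rep(resid, each = nat),
    chain = chain,
    stringsAsFactors = FALSE
  )
  xyz <- matrix(NA_real_, nat * n_res, 3L)
  for (i in seq_len(n_res)) {
    off <- (i - 1L) * nat
    if (cb) {
      cb_i <- synthesize_cb(N[i, ], CA[i, ], C[i, ])
      xyz[off + 1L, ] <- N[i, ]
      xyz[off + 2L, ] <- CA[i, ]
      xyz[off + 3L, ] <- cb_i
      xyz[off + 4L, ] <- C[i, ]
      xyz[off + 5L, ] <- O[i, ]
    } else {
      xyz[off + 1L, ] <- N[i, ]
      xyz[off + 2L, ] <- CA[i, ]
      xyz[off + 3L, ] <- C[i, ]
      xyz[off + 4L, ] <- O[i, ]
    }
  }
  structure3d(atoms, xyz)
}

# Random rigid motion (rotation + translation), used by tests and
# synthetic generators. Returns a function(coords) -> coords.
random_rigid_motion <- function(max_shift = 20) {
  ax <- unitv(stats::rnorm(3L))
  th <- stats::runif(1L, 0, 2 * pi)
  K <- matrix(c(0, -ax[3L], ax[2L], ax[3L], 0, -ax[1L], -ax[2L], ax[1L], 0), 3L, 3L)
  R <- diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  t <- stats::runif(3L, -max_shift, max_shift)
  function(xyz) sweep(xyz %*% t(R), 2L, -t)
}
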