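# Internal-coordinate geometry used by the synthetic structure builders and
# the amide-hydrogen placement step.

#' @keywords internal
vnorm <- function(v) sqrt(sum(v * v))

#' @keywords internal
unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

#' Place an atom from internal coordinates
#'
#' Natural-extension-reference-frame (NeRF) placement: given three previously
#' placed atoms `a`, `b`, `c`, returns the position `d` such that
#' `|c-d| = bond`, the angle b-c-d equals `angle` and the dihedral a-b-c-d
#' equals `dihedral` (both in degrees).
#'
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(dih), sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' @keywords internal
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Standard trans-peptide bond lengths (angstrom) and angles (degrees).
.bb_geom <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8
)

#' Build a peptide backbone from dihedral angles
#'
#' Constructs N, CA, C, O coordinates for `n` residues with per-residue
#' `phi`, `psi` and `omega` dihedrals (degrees), using standard trans-peptide
#' bond geometry. `phi[1]` and the trailing `psi`/`omega` that would require
#' atoms outside the chain are ignored.
#'
#' @param phi,psi,omega numeric vectors of length `n` (recycled if length 1).
#' @return list of `n x 3` matrices `N`, `CA`, `C`, `O`.
#' @keywords internal
build_backbone <- function(n, phi, psi, omega = 180) {
  stopifnot(n >= 2)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n); omega <- rep_len(omega, n)
  g <- .bb_geom
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  # seed frame for residue 1
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  a <- g$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(a), sin(a), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_n, g$ang_ca_c_n, psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], g$n_ca, g$ang_c_n_ca, omega[i])
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$ca_c, g$ang_n_ca_c, phi[i + 1])
  }
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o, psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

#' Side-chain pseudo-atom direction (CA -> CB) for residue i
#'
#' Tetrahedral CB placement from the backbone frame; used to orient the
#' single reactive pseudo-atom that stands in for the lysine side chain.
#'
#' @keywords internal
cbeta_direction <- function(N, CA, C) {
  cb <- place_atom(N, C, CA, bond = 1.53, angle = 110.6, dihedral = 122.6)
  unit(cb - CA)
}
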