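#' Ideal backbone geometry used by the chain builder
#'
#' Bond lengths in Angstrom, angles in degrees. Trans peptide bonds
#' (omega = 180) are used for all residues including pre-proline;
#' cis-proline sampling is a documented limitation.
#'
#' @return named list of bond lengths and angles.
#' @export
ideal_geometry <- function() {
  list(
    b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
    b_c_o = 1.231, b_ca_cb = 1.530,
    a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
    a_ca_c_o = 120.5, a_n_ca_cb = 110.4,
    omega = 180
  )
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention: looking down the central bond (p2 -> p3), the
#' angle is positive for a clockwise rotation of p4 relative to p1;
#' a planar trans arrangement gives 180 degrees, planar cis gives 0.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (!all(is.finite(c(b1, b2, b3)))) stop("non-finite coordinates")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  y <- sum(cross3(n1, n2) * unit3(b2))
  wrap_angle(atan2(y, sum(n1 * n2)) * 180 / pi)
}

## NeRF placement: position atom D bonded to C, with bond length `bond`,
## bond angle B-C-D `angle` (deg) and torsion A-B-C-D `torsion` (deg).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Realize one frame of backbone dihedrals as 3-D coordinates
#'
#' Builds an all-backbone conformation (N, CA, C, O per residue, plus a
#' CB-like pseudo-atom for non-glycine residues) by sequential
#' internal-coordinate placement (natural-extension reference frame).
#' phi of residue 1 and psi of residue L are not defined by the chain;
#' any values supplied there are ignored and fixed extended-region
#' placeholders are used for the atoms they would position.
#'
#' @param phi,psi numeric vectors of length L (degrees); `phi[1]` and
#'   `psi[L]` may be `NA`.
#' @param sequence a `peptide_sequence` (or string) giving residue
#'   identities; glycines receive no pseudo-CB.
#' @param geometry ideal geometry list, see [ideal_geometry()].
#' @param omega peptide-bond torsion in degrees, default 180 (trans).
#' @return an object of class `conformation`: list with `xyz` (n_atoms x 3
#'   matrix), `atom` (names), `resno` (1-based residue numbers),
#'   `resid` (one-letter codes), `element`.
#' @export
build_backbone <- function(phi, psi, sequence,
                           geometry = ideal_geometry(), omega = NULL) {
  if (is.character(sequence)) sequence <- peptide_sequence(sequence)
  res <- sequence$residues
  L <- length(res)
  stopifnot(length(phi) == L, length(psi) == L)
  if (is.null(omega)) omega <- geometry$omega
  ## terminal placeholders: extended-region values (analysis never uses them)
  if (is.na(phi[1])) phi[1] <- -120
  if (is.na(psi[L])) psi[L] <- 150
  if (!all(is.finite(c(phi, psi))))
    stop("non-finite dihedral angle supplied")
  g <- geometry

  n_xyz <- matrix(NA_real_, L, 3)
  ca_xyz <- matrix(NA_real_, L, 3)
  c_xyz <- matrix(NA_real_, L, 3)

  ## first residue in a canonical local frame
  n_xyz[1, ] <- c(0, 0, 0)
  ca_xyz[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  c_xyz[1, ] <- ca_xyz[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)

  for (i in seq_len(L - 1)) {
    ## psi_i places N_{i+1}; omega places CA_{i+1}; phi_{i+1} places C_{i+1}
    n_xyz[i + 1, ] <- place_atom(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ],
                                 g$b_c_n, g$a_ca_c_n, psi[i])
    ca_xyz[i + 1, ] <- place_atom(ca_xyz[i, ], c_xyz[i, ], n_xyz[i + 1, ],
                                  g$b_n_ca, g$a_c_n_ca, omega)
    c_xyz[i + 1, ] <- place_atom(c_xyz[i, ], n_xyz[i + 1, ], ca_xyz[i + 1, ],
                                 g$b_ca_c, g$a_n_ca_c, phi[i + 1])
  }

  ## carbonyl O: anti to the next residue's N (torsion psi_i - 180);
  ## for the C-terminal residue use the placeholder psi.
  o_xyz <- matrix(NA_real_, L, 3)
  for (i in seq_len(L)) {
    o_xyz[i, ] <- place_atom(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ],
                             g$b_c_o, g$a_ca_c_o, wrap_angle(psi[i] + 180))
  }
  ## pseudo-CB for non-glycine residues (ideal tetrahedral placement)
  has_cb <- res != "G"
  cb_xyz <- matrix(NA_real_, L, 3)
  for (i in which(has_cb)) {
    cb_xyz[i, ] <- place_atom(c_xyz[i, ], n_xyz[i, ], ca_xyz[i, ],
                              g$b_ca_cb, g$a_n_ca_cb, 122.6)
  }

  atom <- character(0); resno <- integer(0); element <- character(0)
  xyz <- matrix(NA_real_, 0, 3)
  for (i in seq_len(L)) {
    names_i <- c("N", "CA", "C", "O", if (has_cb[i]) "CB")
    xyz_i <- rbind(n_xyz[i, ], ca_xyz[i, ], c_xyz[i, ], o_xyz[i, ],
                   if (has_cb[i]) cb_xyz[i, ])
    atom <- c(atom, names_i)
    resno <- c(resno, rep(i, length(names_i)))
    element <- c(element, substr(names_i, 1, 1))
    xyz <- rbind(xyz, xyz_i)
  }
  structure(list(xyz = xyz, atom = atom, resno = resno,
                 resid = res[resno], element = element,
                 sequence = sequence$sequence),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> %d residues, %d atoms (%s)\n",
              max(x$resno), nrow(x$xyz), x$sequence))
  invisible(x)
}

## Extract coordinates of one named atom per residue, as an L x 3 matrix.
atom_coords <- function(conf, name) {
  idx <- which(conf$atom == name)
  out <- matrix(NA_real_, max(conf$resno), 3)
  out[conf$resno[idx], ] <- conf$xyz[idx, , drop = FALSE]
  out
}

#' Backbone dihedrals of a single conformation
#'
#' phi_i = dihedral(C_{i-1}, N_i, CA_i, C_i),
#' psi_i = dihedral(N_i, CA_i, C_i, N_{i+1}); only interior residues
#' (2..L-1) carry complete (phi, psi) pairs.
#'
#' @param conf a `conformation`.
#' @return data.frame with columns `residue`, `phi`, `psi` for residues
#'   2..L-1, angles in degrees in (-180, 180].
#' @export
conformation_dihedrals <- function(conf) {
  stopifnot(inherits(conf, "conformation"))
  N <- atom_coords(conf, "N")
  CA <- atom_coords(conf, "CA")
  C <- atom_coords(conf, "C")
  L <- max(conf$resno)
  if (anyNA(N) || anyNA(CA) || anyNA(C))
    stop("incomplete backbone: missing N/CA/C atoms")
  interior <- 2:(L - 1)
  phi <- vapply(interior, function(i)
    dihedral_angle(C[i - 1, ], N[i, ], CA[i, ], C[i, ]), 0)
  psi <- vapply(interior, function(i)
    dihedral_angle(N[i, ], CA[i, ], C[i, ], N[i + 1, ]), 0)
  data.frame(residue = interior, phi = phi, psi = psi)
}
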