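## Standard atomic masses (u) and Bondi van der Waals radii (Angstrom)
## for the backbone elements the generator produces.
ATOMIC_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, H = 1.008)
BONDI_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

#' Radius of gyration
#'
#' Mass-weighted RMS distance of atoms from the mass-weighted centroid,
#' `sqrt(sum(m_i |r_i - rbar|^2) / sum(m_i))`.
#'
#' @param conformation a `conformation`, or a plain n x 3 coordinate
#'   matrix.
#' @param masses per-atom masses; default: standard atomic masses by
#'   element for a `conformation`, unit weights for a bare matrix.
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(conformation, masses = NULL) {
  if (inherits(conformation, "conformation")) {
    xyz <- conformation$xyz
    if (is.null(masses)) masses <- ATOMIC_MASS[conformation$element]
  } else {
    xyz <- as.matrix(conformation)
  }
  if (nrow(xyz) < 1) stop("empty conformation")
  if (is.null(masses)) masses <- rep(1, nrow(xyz))
  if (any(masses <= 0) || length(masses) != nrow(xyz))
    stop("masses must be positive, one per atom")
  ctr <- colSums(xyz * masses) / sum(masses)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' End-to-end distance
#'
#' Euclidean distance between the CA atoms of the first and last
#' residues (the most reproducible convention; configurable to
#' N-terminus N to C-terminus C).
#'
#' @param conformation a `conformation`.
#' @param atoms `"ca"` (default, CA(1) to CA(L)) or `"nc"`
#'   (N(1) to C(L)).
#' @return distance in Angstrom.
#' @export
end_to_end_distance <- function(conformation, atoms = c("ca", "nc")) {
  stopifnot(inherits(conformation, "conformation"))
  atoms <- match.arg(atoms)
  L <- max(conformation$resno)
  if (atoms == "ca") {
    ca <- atom_coords(conformation, "CA")
    a <- ca[1, ]; b <- ca[L, ]
  } else {
    a <- atom_coords(conformation, "N")[1, ]
    b <- atom_coords(conformation, "C")[L, ]
  }
  if (anyNA(a) || anyNA(b)) stop("missing terminal backbone atom")
  sqrt(sum((a - b)^2))
}

## Deterministic quasi-uniform points on the unit sphere
## (golden-spiral / Fibonacci lattice).
sphere_lattice <- function(n) {
  k <- seq_len(n) - 0.5
  polar <- acos(1 - 2 * k / n)
  azim <- pi * (1 + sqrt(5)) * (k - 0.5)
  cbind(sin(polar) * cos(azim), sin(polar) * sin(azim), cos(polar))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Point-counting SASA: each atom's sphere is expanded by the probe
#' radius and covered with a deterministic spiral lattice of test
#' points; a point is buried if it falls inside any neighbouring
#' expanded sphere. SASA is the summed exposed fraction times
#' `4 pi (r_i + probe)^2`.
#'
#' @param conformation a `conformation`, or an n x 3 coordinate matrix
#'   (then `radii` is required).
#' @param radii per-atom van der Waals radii (Angstrom); default Bondi
#'   radii by element.
#' @param probe probe radius in Angstrom, default 1.4 (water).
#' @param n_sphere_points test points per atom, default 960; fewer than
#'   32 is rejected as below the accuracy floor.
#' @return solvent accessible surface area in Angstrom^2.
#' @export
sasa_shrake_rupley <- function(conformation, radii = NULL, probe = 1.4,
                               n_sphere_points = 960) {
  if (n_sphere_points < 32) stop("n_sphere_points must be >= 32")
  if (probe < 0) stop("probe radius must be >= 0")
  if (inherits(conformation, "conformation")) {
    xyz <- conformation$xyz
    if (is.null(radii)) radii <- BONDI_RADII[conformation$element]
  } else {
    xyz <- as.matrix(conformation)
    if (is.null(radii)) stop("radii required for bare coordinate input")
  }
  n <- nrow(xyz)
  if (length(radii) == 1L) radii <- rep(radii, n)
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("radii must be positive and finite")
  R <- radii + probe
  pts <- sphere_lattice(n_sphere_points)
  total <- 0
  for (i in seq_len(n)) {
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
      exposed <- exposed & dj2 >= R[j]^2
    }
    total <- total + mean(exposed) * 4 * pi * R[i]^2
  }
  total
}

#' Per-frame compactness records for an ensemble
#'
#' @param ensemble an `ensemble` carrying coordinates.
#' @param probe,n_sphere_points passed to [sasa_shrake_rupley()].
#' @return object of class `compactness_records`: data.frame with
#'   columns `frame`, `replica`, `rg`, `ree`, `sasa`.
#' @export
compactness_records <- function(ensemble, probe = 1.4,
                                n_sphere_points = 960) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (is.null(ensemble$conformations))
    stop("ensemble has no coordinates; regenerate with coords = TRUE")
  n <- length(ensemble$conformations)
  out <- data.frame(
    frame = seq_len(n),
    replica = ensemble$replica,
    rg = vapply(ensemble$conformations, radius_of_gyration, 0),
    ree = vapply(ensemble$conformations, end_to_end_distance, 0),
    sasa = vapply(ensemble$conformations, sasa_shrake_rupley, 0,
                  probe = probe, n_sphere_points = n_sphere_points)
  )
  class(out) <- c("compactness_records", "data.frame")
  out
}

#' Replica-structured summary of a per-frame metric
#'
#' Replica means are computed first; the grand mean and the spread
#' (standard deviation and standard error) are taken across replica
#' means, not across pooled frames.
#'
#' @param values numeric vector of per-frame values.
#' @param replica per-frame replica labels.
#' @return list with `replica_means` (named), `grand_mean`, `sd`, `sem`,
#'   `n_replicas`.
#' @export
summarize_by_replica <- function(values, replica) {
  stopifnot(length(values) == length(replica))
  if (!length(values)) stop("no frames")
  keep <- !is.na(values)
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " NA frame value(s)")
    values <- values[keep]; replica <- replica[keep]
  }
  means <- tapply(values, replica, mean)
  nrep <- length(means)
  s <- if (nrep > 1) stats::sd(means) else 0
  list(replica_means = means,
       grand_mean = mean(means),
       sd = s,
       sem = s / sqrt(nrep),
       n_replicas = nrep)
}

#' Ensemble-level compactness summary
#'
#' @param records a `compactness_records` data.frame.
#' @return object of class `ensemble_summary`: named list (rg, ree,
#'   sasa) of [summarize_by_replica()] results.
#' @export
ensemble_summary <- function(records) {
  stopifnot(all(c("replica", "rg", "ree", "sasa") %in% names(records)))
  out <- lapply(c(rg = "rg", ree = "ree", sasa = "sasa"), function(m)
    summarize_by_replica(records[[m]], records$replica))
  structure(out, class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("<ensemble_summary> (grand mean of replica means +/- SEM)\n")
  for (m in names(x))
    cat(sprintf("  %-5s %8.3f +/- %.3f  (%d replicas)\n",
                m, x[[m]]$grand_mean, x[[m]]$sem, x[[m]]$n_replicas))
  invisible(x)
}
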