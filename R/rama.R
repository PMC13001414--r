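#' Default five-region Ramachandran map
#'
#' Four named regions (alphaR, alphaL, beta, PPII), each a set of
#' half-open axis-aligned rectangles on the wrapped (phi, psi) torus; the
#' implicit fifth class "unassigned" is the complement. Rectangles are
#' lower-edge inclusive, upper-edge exclusive, applied after wrapping
#' angles into (-180, 180]. Upper bounds may exceed 180 to express
#' intervals that wrap around the seam (e.g. psi in [100, 200) means
#' psi >= 100 or psi < -160).
#'
#' The boundaries are package defaults: documented, validated for
#' pairwise disjointness, and fully user-overridable; every statistic in
#' the package is self-consistent under any valid replacement map.
#'
#' @return object of class `region_map`: named list of data.frames with
#'   columns `phi_lo`, `phi_hi`, `psi_lo`, `psi_hi`.
#' @export
default_region_map <- function() {
  rect <- function(phi_lo, phi_hi, psi_lo, psi_hi)
    data.frame(phi_lo = phi_lo, phi_hi = phi_hi,
               psi_lo = psi_lo, psi_hi = psi_hi)
  structure(list(
    alphaR = rect(-160, -20, -120, 50),
    alphaL = rect(20, 160, -50, 120),
    beta   = rect(-180, -100, 100, 200),
    PPII   = rect(-100, -20, 100, 200)
  ), class = "region_map")
}

## membership of wrapped angle `a` in the circular interval [lo, hi)
in_arc <- function(a, lo, hi) {
  ((a - lo) %% 360) < (hi - lo)
}

#' Validate a region map
#'
#' Checks rectangle sanity and pairwise disjointness of the named regions
#' by a dense grid scan.
#'
#' @param map a `region_map`.
#' @param resolution grid spacing in degrees for the disjointness scan.
#' @return `map`, invisibly; errors if invalid.
#' @export
validate_region_map <- function(map, resolution = 2) {
  if (!all(names(map) %in% setdiff(RAMA_CLASSES, "unassigned")) ||
      length(map) == 0)
    stop("region map names must be among: ",
         paste(setdiff(RAMA_CLASSES, "unassigned"), collapse = ", "))
  for (nm in names(map)) {
    r <- map[[nm]]
    if (!all(c("phi_lo", "phi_hi", "psi_lo", "psi_hi") %in% names(r)))
      stop("region ", nm, ": rectangles need phi_lo/phi_hi/psi_lo/psi_hi")
    if (any(r$phi_hi <= r$phi_lo) || any(r$psi_hi <= r$psi_lo))
      stop("region ", nm, ": degenerate rectangle")
    if (any(r$phi_hi - r$phi_lo > 360) || any(r$psi_hi - r$psi_lo > 360))
      stop("region ", nm, ": rectangle wider than the torus")
  }
  g <- seq(-180 + resolution / 2, 180, by = resolution)
  grid <- expand.grid(phi = g, psi = g)
  hits <- matrix(0L, nrow(grid), length(map))
  for (k in seq_along(map)) {
    r <- map[[k]]
    inside <- rep(FALSE, nrow(grid))
    for (j in seq_len(nrow(r))) {
      inside <- inside |
        (in_arc(grid$phi, r$phi_lo[j], r$phi_hi[j]) &
         in_arc(grid$psi, r$psi_lo[j], r$psi_hi[j]))
    }
    hits[, k] <- as.integer(inside)
  }
  if (any(rowSums(hits) > 1L))
    stop("region map regions overlap (grid scan at ", resolution, " deg)")
  invisible(map)
}

#' Classify backbone dihedrals into five Ramachandran classes
#'
#' Deterministic, total after wrapping: every (phi, psi) pair receives
#' exactly one of alphaR, alphaL, beta, PPII or unassigned. Boundary
#' points follow the half-open rectangle convention (lower edge
#' inclusive).
#'
#' @param phi,psi numeric vectors of angles in degrees (any range; they
#'   are wrapped into (-180, 180]).
#' @param map a `region_map`, default [default_region_map()].
#' @return factor with levels `alphaR, alphaL, beta, PPII, unassigned`.
#' @export
#' @examples
#' classify_rama(-60, -45)  # alphaR
#' classify_rama(-75, 150)  # PPII
classify_rama <- function(phi, psi, map = default_region_map()) {
  stopifnot(length(phi) == length(psi))
  if (any(!is.finite(phi)) || any(!is.finite(psi)))
    stop("non-finite dihedral angles")
  phi <- wrap_angle(phi)
  psi <- wrap_angle(psi)
  out <- rep("unassigned", length(phi))
  for (nm in names(map)) {
    r <- map[[nm]]
    inside <- rep(FALSE, length(phi))
    for (j in seq_len(nrow(r))) {
      inside <- inside |
        (in_arc(phi, r$phi_lo[j], r$phi_hi[j]) &
         in_arc(psi, r$psi_lo[j], r$psi_hi[j]))
    }
    out[inside & out == "unassigned"] <- nm
  }
  factor(out, levels = RAMA_CLASSES)
}

#' Per-residue Ramachandran-class occupancies, per replica
#'
#' For every interior residue and replica, the fraction of frames spent
#' in each of the five classes.
#'
#' @param series a `dihedral_series` (see [sample_dihedrals()] /
#'   [compute_dihedrals()]).
#' @param map a `region_map`.
#' @return object of class `occupancy_set`: 3-D array
#'   `[residue, class, replica]` of fractions, with attributes `variant`
#'   and `n_frames` (frames per replica).
#' @export
occupancy <- function(series, map = default_region_map()) {
  stopifnot(inherits(series, "dihedral_series"))
  if (nrow(series$phi) == 0) stop("empty dihedral series")
  reps <- sort(unique(series$replica))
  nres <- ncol(series$phi)
  out <- array(0, dim = c(nres, length(RAMA_CLASSES), length(reps)),
               dimnames = list(residue = series$residues,
                               class = RAMA_CLASSES,
                               replica = reps))
  nf <- integer(length(reps))
  for (k in seq_along(reps)) {
    sel <- series$replica == reps[k]
    nf[k] <- sum(sel)
    for (r in seq_len(nres)) {
      cl <- classify_rama(series$phi[sel, r], series$psi[sel, r], map)
      out[r, , k] <- tabulate(cl, nbins = length(RAMA_CLASSES)) / nf[k]
    }
  }
  structure(out, class = "occupancy_set",
            variant = series$label, n_frames = nf)
}

#' Average occupancy profiles across replicas
#'
#' Unweighted mean over replicas, with both standard deviation and
#' standard error of the replica values per residue-class cell.
#'
#' @param occ an `occupancy_set`, or a list of residue x class occupancy
#'   matrices of identical shape.
#' @return object of class `occupancy_summary`: list with `mean`, `sd`,
#'   `sem` (residue x class matrices) and `n_replicas`.
#' @export
average_profiles <- function(occ) {
  if (inherits(occ, "occupancy_set")) {
    arr <- unclass(occ)
  } else if (is.list(occ)) {
    shapes <- vapply(occ, function(m) paste(dim(m), collapse = "x"), "")
    if (length(unique(shapes)) != 1L)
      stop("profiles have inconsistent shapes")
    arr <- array(unlist(occ), dim = c(dim(occ[[1]]), length(occ)),
                 dimnames = c(dimnames(occ[[1]]), list(NULL)))
  } else stop("unsupported input")
  n <- dim(arr)[3]
  m <- apply(arr, c(1, 2), mean)
  s <- if (n > 1) apply(arr, c(1, 2), stats::sd) else m * 0
  structure(list(mean = m, sd = s, sem = s / sqrt(n), n_replicas = n,
                 variant = attr(occ, "variant")),
            class = "occupancy_summary")
}

#' Variant-vs-wild-type secondary-structure deviation profile
#'
#' Per residue and class, the difference of replica-averaged occupancies
#' (variant minus wild type) with combined uncertainty
#' sqrt(SEM_variant^2 + SEM_wt^2). Because both inputs are
#' row-normalized, the five deviations at each residue sum to zero.
#'
#' @param variant,wild_type `occupancy_summary` objects of matching shape.
#' @return object of class `deviation_profile`: list with `delta` and
#'   `uncertainty` (residue x class matrices).
#' @export
deviation_profile <- function(variant, wild_type) {
  stopifnot(inherits(variant, "occupancy_summary"),
            inherits(wild_type, "occupancy_summary"))
  if (!identical(dim(variant$mean), dim(wild_type$mean)))
    stop("profile shape mismatch")
  structure(list(
    delta = variant$mean - wild_type$mean,
    uncertainty = sqrt(variant$sem^2 + wild_type$sem^2),
    variant = variant$variant, wild_type = wild_type$variant
  ), class = "deviation_profile")
}
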