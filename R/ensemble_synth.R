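#' Default Ramachandran basin specifications for the generator
#'
#' Wrapped bivariate-normal basins, one per named Ramachandran class.
#' Centers and spreads are chosen so each basin sits at least 2.5 sigma
#' inside its region of [default_region_map()], which makes the
#' generating propensities recoverable by classification up to small
#' tail leakage.
#'
#' @return named list of basins, each `list(center = c(phi, psi),
#'   spread = c(sd_phi, sd_psi))` in degrees.
#' @export
default_basins <- function() {
  list(
    alphaR = list(center = c(-60, -45), spread = c(10, 10)),
    alphaL = list(center = c(60, 45), spread = c(10, 10)),
    beta   = list(center = c(-135, 145), spread = c(12, 12)),
    PPII   = list(center = c(-75, 150), spread = c(10, 12))
  )
}

## Per-residue default class weights (alphaR, alphaL, beta, PPII,
## unassigned). Disorder-dominated, beta/PPII-rich baseline; glycine is
## alphaL-accessible; proline is PPII-biased with zero beta weight
## because its restricted phi (center -65) cannot reach the beta region.
aa_default_weights <- function(aa) {
  w <- switch(aa,
    G = c(0.12, 0.20, 0.25, 0.23, 0.20),
    P = c(0.05, 0.00, 0.00, 0.90, 0.05),
    c(0.15, 0.05, 0.35, 0.35, 0.10))
  names(w) <- RAMA_CLASSES
  w
}

## Helix-propensity-inspired alphaR increments used by the demo variant
## effect model (applied at the mutated position; mass is taken
## proportionally from beta and PPII). Values are package defaults for
## synthetic panels, loosely ordered like experimental helix scales.
AA_HELIX_DELTA <- c(
  A = 0.10, L = 0.08, M = 0.08, E = 0.07, R = 0.06, K = 0.06, Q = 0.06,
  I = 0.04, W = 0.04, F = 0.04, S = 0.02, Y = 0.02, H = 0.02, C = 0.02,
  D = 0.02, V = 0.00, T = 0.00, N = 0.00, G = -0.05, P = -0.05
)

#' Construct / validate a per-residue propensity profile
#'
#' A propensity profile holds one weight vector over the five
#' Ramachandran classes per interior residue (positions 2..L-1; terminal
#' residues carry no complete dihedral pair and are excluded).
#'
#' @param weights numeric matrix, rows = interior residues, columns the
#'   five classes in the order `alphaR, alphaL, beta, PPII, unassigned`.
#'   Rows must be non-negative and sum to 1.
#' @param residues integer vector of 1-based residue indices for the
#'   rows, default `2:(nrow + 1)`.
#' @return object of class `propensity_profile` (the validated matrix
#'   with a `residues` attribute).
#' @export
propensity_profile <- function(weights, residues = NULL) {
  weights <- as.matrix(weights)
  if (ncol(weights) != length(RAMA_CLASSES))
    stop("profile needs ", length(RAMA_CLASSES), " class columns")
  colnames(weights) <- RAMA_CLASSES
  if (any(weights < 0)) stop("negative propensity weight")
  if (any(abs(rowSums(weights) - 1) > 1e-8))
    stop("propensity rows must sum to 1")
  if (is.null(residues)) residues <- seq_len(nrow(weights)) + 1L
  stopifnot(length(residues) == nrow(weights))
  rownames(weights) <- residues
  structure(weights, residues = as.integer(residues),
            class = "propensity_profile")
}

#' Default propensity profile for a sequence
#'
#' Residue-specific defaults ([aa_default_weights()]) with an optional
#' helix-propensity adjustment at one position, used to give synthetic
#' variant panels a graded, sequence-dependent signal.
#'
#' @param sequence a `peptide_sequence` or string.
#' @param mutate_position optional 1-based position at which the
#'   amino-acid-specific alphaR increment [AA_HELIX_DELTA] is applied
#'   (mass moved from beta and PPII proportionally).
#' @return a `propensity_profile` over interior residues.
#' @export
default_propensity_profile <- function(sequence, mutate_position = NULL) {
  if (is.character(sequence)) sequence <- peptide_sequence(sequence)
  res <- sequence$residues
  L <- length(res)
  interior <- 2:(L - 1)
  w <- t(vapply(res[interior], aa_default_weights,
                numeric(length(RAMA_CLASSES))))
  if (!is.null(mutate_position) && mutate_position %in% interior) {
    i <- match(mutate_position, interior)
    d <- AA_HELIX_DELTA[[res[mutate_position]]]
    wi <- w[i, ]
    take <- wi[c("beta", "PPII")]
    d <- max(min(d, sum(take) - 1e-6), -wi[["alphaR"]])
    wi[c("beta", "PPII")] <- take - d * take / sum(take)
    wi["alphaR"] <- wi[["alphaR"]] + d
    w[i, ] <- wi / sum(wi)
  }
  propensity_profile(w, interior)
}

#' Shift one class weight of a propensity profile
#'
#' Adds `shift` to `class` at `residue`, removing the same mass from the
#' other classes proportionally; used to inject known perturbations for
#' parameter-recovery and ranking studies.
#'
#' @param profile a `propensity_profile`.
#' @param residue 1-based residue index (must be interior).
#' @param class one of the five class names.
#' @param shift amount to add (may be negative).
#' @return modified `propensity_profile`.
#' @export
shift_propensity <- function(profile, residue, class, shift) {
  stopifnot(inherits(profile, "propensity_profile"),
            class %in% RAMA_CLASSES)
  residues <- attr(profile, "residues")
  i <- match(residue, residues)
  if (is.na(i)) stop("residue ", residue, " not in profile")
  w <- unclass(profile)
  wi <- w[i, ]
  others <- setdiff(RAMA_CLASSES, class)
  if (wi[class] + shift < 0 || wi[class] + shift > 1)
    stop("shift drives weight outside [0, 1]")
  wi[others] <- wi[others] * (1 - (wi[class] + shift)) /
    max(sum(wi[others]), .Machine$double.eps)
  wi[class] <- wi[class] + shift
  w[i, ] <- wi / sum(wi)
  propensity_profile(w, residues)
}

## Draw n angles from a wrapped normal.
rwrapnorm <- function(n, center, sd) {
  wrap_angle(stats::rnorm(n, center, sd))
}

#' Sample a synthetic backbone dihedral series
#'
#' For each frame and interior residue a Ramachandran class is drawn from
#' the profile weights, then (phi, psi) from the class's wrapped
#' bivariate normal basin; "unassigned" draws uniformly from the
#' complement of the named regions by rejection. Frames are i.i.d. by
#' default; `mixing` > 0 holds the previous frame's class with that
#' probability (first-order autocorrelation stress-test, off by
#' default). Proline phi is drawn from N(-65, 8) regardless of class
#' (restricted phi).
#'
#' @param profile a `propensity_profile`.
#' @param basins basin list, default [default_basins()].
#' @param n_frames number of frames (> 0).
#' @param seed integer RNG seed; same seed gives identical output.
#' @param sequence optional `peptide_sequence` (or string) enabling the
#'   proline phi restriction; also carried as metadata.
#' @param map `region_map` used by the rejection sampler for the
#'   unassigned class.
#' @param mixing probability of holding the previous class, in [0, 1).
#' @param replica replica id stored with every frame (default 1).
#' @return object of class `dihedral_series`: list with `phi`, `psi`
#'   (n_frames x n_residues matrices, degrees), `residues` (1-based
#'   indices), `replica` (per-frame ids), `label`.
#' @export
sample_dihedrals <- function(profile, basins = default_basins(),
                             n_frames, seed,
                             sequence = NULL,
                             map = default_region_map(),
                             mixing = 0, replica = 1L) {
  stopifnot(inherits(profile, "propensity_profile"))
  if (n_frames <= 0) stop("n_frames must be positive")
  stopifnot(mixing >= 0, mixing < 1)
  active <- colnames(profile)[apply(unclass(profile) > 0, 2, any)]
  missing_basin <- setdiff(setdiff(active, "unassigned"), names(basins))
  if (length(missing_basin))
    stop("no basin specification for class(es): ",
         paste(missing_basin, collapse = ", "))
  if (is.character(sequence)) sequence <- peptide_sequence(sequence)
  residues <- attr(profile, "residues")
  res_codes <- if (!is.null(sequence)) sequence$residues[residues] else
    rep("X", length(residues))
  w <- unclass(profile)
  nres <- length(residues)

  with_seed(seed, {
    phi <- matrix(NA_real_, n_frames, nres)
    psi <- matrix(NA_real_, n_frames, nres)
    for (r in seq_len(nres)) {
      cls <- sample.int(length(RAMA_CLASSES), n_frames, replace = TRUE,
                        prob = w[r, ])
      if (mixing > 0 && n_frames > 1) {
        hold <- stats::runif(n_frames) < mixing
        for (t in 2:n_frames) if (hold[t]) cls[t] <- cls[t - 1]
      }
      is_pro <- res_codes[r] == "P"
      for (k in seq_along(RAMA_CLASSES)) {
        idx <- which(cls == k)
        if (!length(idx)) next
        cl_name <- RAMA_CLASSES[k]
        if (cl_name == "unassigned") {
          ## rejection sampling from the complement region
          need <- idx
          while (length(need)) {
            cand_phi <- if (is_pro) rwrapnorm(length(need), -65, 8) else
              stats::runif(length(need), -180, 180)
            cand_psi <- stats::runif(length(need), -180, 180)
            ok <- classify_rama(cand_phi, cand_psi, map) == "unassigned"
            phi[need[ok], r] <- cand_phi[ok]
            psi[need[ok], r] <- cand_psi[ok]
            need <- need[!ok]
          }
        } else {
          b <- basins[[cl_name]]
          phi[idx, r] <- if (is_pro) rwrapnorm(length(idx), -65, 8) else
            rwrapnorm(length(idx), b$center[1], b$spread[1])
          psi[idx, r] <- rwrapnorm(length(idx), b$center[2], b$spread[2])
        }
      }
    }
    structure(list(phi = phi, psi = psi, residues = residues,
                   replica = rep(as.integer(replica), n_frames),
                   label = if (!is.null(sequence)) sequence$label else NA_character_,
                   sequence = if (!is.null(sequence)) sequence$sequence else NULL),
              class = "dihedral_series")
  })
}

#' @export
print.dihedral_series <- function(x, ...) {
  cat(sprintf("<dihedral_series> %d frames x %d residues (%d replica%s)%s\n",
              nrow(x$phi), ncol(x$phi), length(unique(x$replica)),
              if (length(unique(x$replica)) == 1) "" else "s",
              if (is.na(x$label)) "" else paste0(", ", x$label)))
  invisible(x)
}

## Concatenate dihedral series frame-wise (shared residue set).
bind_series <- function(series_list) {
  s1 <- series_list[[1]]
  structure(list(
    phi = do.call(rbind, lapply(series_list, `[[`, "phi")),
    psi = do.call(rbind, lapply(series_list, `[[`, "psi")),
    residues = s1$residues,
    replica = unlist(lapply(series_list, `[[`, "replica")),
    label = s1$label, sequence = s1$sequence
  ), class = "dihedral_series")
}

#' Generate a multi-replica synthetic ensemble for one variant
#'
#' Draws `n_replicas` independent dihedral series (replica i uses seed
#' `seed + i`, a stable documented derivation) and optionally realizes
#' every frame as backbone coordinates via [build_backbone()].
#'
#' @param variant a `peptide_sequence` or string.
#' @param profile a `propensity_profile`; default
#'   [default_propensity_profile()] of the variant.
#' @param n_replicas number of replicas, default 16 (the study design).
#' @param n_frames frames per replica.
#' @param seed master seed.
#' @param coords logical; build 3-D conformations (needed for
#'   compactness metrics, slower). Default FALSE.
#' @param basins,map,mixing passed to [sample_dihedrals()].
#' @return object of class `ensemble`: list with `sequence`
#'   (`peptide_sequence`), `dihedrals` (`dihedral_series` over all
#'   frames), `replica` (per-frame ids), and `conformations` (list of
#'   `conformation`, or NULL).
#' @export
generate_ensemble <- function(variant, profile = NULL,
                              n_replicas = 16, n_frames = 1000, seed = 1,
                              coords = FALSE,
                              basins = default_basins(),
                              map = default_region_map(),
                              mixing = 0) {
  if (is.character(variant)) variant <- peptide_sequence(variant)
  if (n_replicas < 1) stop("n_replicas must be >= 1")
  if (is.null(profile)) profile <- default_propensity_profile(variant)
  series <- lapply(seq_len(n_replicas), function(i) {
    sample_dihedrals(profile, basins, n_frames, seed = seed + i,
                     sequence = variant, map = map, mixing = mixing,
                     replica = i)
  })
  dih <- bind_series(series)
  confs <- NULL
  if (coords) {
    L <- length(variant$residues)
    interior <- dih$residues
    confs <- lapply(seq_len(nrow(dih$phi)), function(f) {
      phi <- rep(NA_real_, L); psi <- rep(NA_real_, L)
      phi[interior] <- dih$phi[f, ]
      psi[interior] <- dih$psi[f, ]
      ## terminal dihedrals not part of the statistical model: fixed
      ## extended-region values (see build_backbone)
      psi[1] <- 150; phi[L] <- -120
      build_backbone(phi, psi, variant)
    })
  }
  structure(list(sequence = variant, dihedrals = dih,
                 replica = dih$replica, conformations = confs,
                 label = variant$label),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %s: %d frames, %d replicas%s\n",
              x$label, nrow(x$dihedrals$phi), length(unique(x$replica)),
              if (is.null(x$conformations)) " (dihedrals only)" else
                " (with coordinates)"))
  invisible(x)
}

#' Backbone dihedrals of an ensemble
#'
#' Extracts (phi, psi) for interior residues from every stored
#' conformation. For dihedral-only ensembles the generated series is
#' returned directly.
#'
#' @param ensemble an `ensemble`.
#' @return a `dihedral_series`.
#' @export
compute_dihedrals <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (is.null(ensemble$conformations)) return(ensemble$dihedrals)
  L <- length(ensemble$sequence$residues)
  interior <- 2:(L - 1)
  n <- length(ensemble$conformations)
  phi <- matrix(NA_real_, n, length(interior))
  psi <- matrix(NA_real_, n, length(interior))
  for (f in seq_len(n)) {
    d <- conformation_dihedrals(ensemble$conformations[[f]])
    phi[f, ] <- d$phi
    psi[f, ] <- d$psi
  }
  structure(list(phi = phi, psi = psi, residues = interior,
                 replica = ensemble$replica, label = ensemble$label,
                 sequence = ensemble$sequence$sequence),
            class = "dihedral_series")
}
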