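#' Default 5-to-3 class grouping for feature construction
#'
#' The three broad secondary-structure classes used for multivariate
#' comparison: right-handed helix, combined beta/PPII, and unstructured
#' (left-handed helix merged with unassigned; alphaL is a minority class
#' for non-glycine residues, so folding it into "unstructured" is the
#' conservative reading).
#'
#' @return named list mapping feature names to the five-class labels
#'   they pool.
#' @export
default_grouping <- function() {
  list(alphaR = "alphaR",
       betaPPII = c("beta", "PPII"),
       unstructured = c("alphaL", "unassigned"))
}

#' Build the per-trajectory feature matrix
#'
#' One row per trajectory (variant x replica); columns are the grouped
#' per-residue occupancies in residue-major, class-minor order, so an
#' L-residue peptide yields `3 * (L - 2)` columns under the default
#' grouping. Per-residue triplets each sum to 1.
#'
#' @param occ_sets list of `occupancy_set` objects (one per variant), or
#'   a single `occupancy_set`.
#' @param grouping a partition of the five classes,
#'   default [default_grouping()].
#' @return object of class `feature_matrix`: numeric matrix with
#'   attributes `variant` and `replica` (row metadata vectors).
#' @export
build_features <- function(occ_sets, grouping = default_grouping()) {
  if (inherits(occ_sets, "occupancy_set")) occ_sets <- list(occ_sets)
  pooled <- sort(unname(unlist(grouping)))
  if (!identical(pooled, sort(RAMA_CLASSES)))
    stop("grouping must partition the five classes exactly")
  rows <- list(); variant <- character(0); replica <- integer(0)
  for (occ in occ_sets) {
    arr <- unclass(occ)
    reps <- dimnames(arr)$replica
    resn <- dimnames(arr)$residue
    for (k in seq_along(reps)) {
      m <- matrix(arr[, , k], nrow = dim(arr)[1],
                  dimnames = dimnames(arr)[1:2])    # residue x 5
      g <- vapply(grouping, function(cls)
        rowSums(m[, cls, drop = FALSE]), numeric(nrow(m)))
      v <- as.vector(t(g))                          # residue-major
      names(v) <- paste0("r", rep(resn, each = length(grouping)),
                         "_", rep(names(grouping), length(resn)))
      rows[[length(rows) + 1L]] <- v
      variant <- c(variant, attr(occ, "variant"))
      replica <- c(replica, as.integer(reps[k]))
    }
  }
  X <- do.call(rbind, rows)
  rownames(X) <- paste(variant, replica, sep = "|")
  structure(X, variant = variant, replica = replica,
            grouping = grouping, class = c("feature_matrix", "matrix"))
}

#' Fit a PCA model to a feature matrix
#'
#' Columns are centered (no scaling by default: occupancies are already
#' commensurate fractions) and decomposed by SVD. Component signs are
#' fixed so the largest-magnitude loading of each component is positive.
#' A rank-0 input (all rows identical) yields a valid model with zero
#' explained variance rather than an error.
#'
#' @param X a `feature_matrix` or numeric matrix, >= 2 rows.
#' @param scale. logical; standardize columns before the fit (columns
#'   with zero variance are left unscaled). Default FALSE.
#' @return object of class `ssp_pca`: list with `center`, `scale`,
#'   `rotation` (columns = components), `sdev`, `var_explained`.
#' @export
fit_pca <- function(X, scale. = FALSE) {
  X <- unclass(X)
  if (nrow(X) < 2) stop("PCA needs at least 2 rows")
  if (any(!is.finite(X))) stop("non-finite feature values")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- NULL
  if (scale.) {
    scl <- apply(Xc, 2, stats::sd)
    scl[scl == 0] <- 1
    Xc <- sweep(Xc, 2, scl, "/")
  }
  k <- min(dim(Xc))
  sv <- svd(Xc, nu = 0, nv = k)
  sdev <- sv$d[seq_len(k)] / sqrt(nrow(X) - 1)
  rot <- sv$v
  ## sign convention: largest |loading| positive per component
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  colnames(rot) <- paste0("PC", seq_len(ncol(rot)))
  rownames(rot) <- colnames(X)
  tot <- sum(sdev^2)
  ve <- if (tot > 0) sdev^2 / tot else rep(0, length(sdev))
  structure(list(center = ctr, scale = scl, rotation = rot,
                 sdev = sdev, var_explained = ve),
            class = "ssp_pca")
}

#' @export
print.ssp_pca <- function(x, ...) {
  cat(sprintf("<ssp_pca> %d components; PC1 %.1f%%, PC2 %.1f%% variance\n",
              ncol(x$rotation), 100 * x$var_explained[1],
              100 * ifelse(length(x$var_explained) > 1,
                           x$var_explained[2], 0)))
  invisible(x)
}

#' Project feature rows into principal-component space
#'
#' @param model an `ssp_pca`.
#' @param rows numeric matrix (or single vector) with the model's
#'   column count.
#' @param k number of leading components, default 2.
#' @return matrix of scores, one row per input row, `k` columns; row
#'   metadata attributes (`variant`, `replica`) are propagated when
#'   present on `rows`.
#' @export
project_pca <- function(model, rows, k = 2) {
  stopifnot(inherits(model, "ssp_pca"))
  meta_v <- attr(rows, "variant"); meta_r <- attr(rows, "replica")
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1)
  rows <- unclass(rows)
  if (ncol(rows) != length(model$center))
    stop("column count mismatch: ", ncol(rows), " vs ",
         length(model$center))
  if (k > ncol(model$rotation)) stop("k exceeds number of components")
  Xc <- sweep(rows, 2, model$center)
  if (!is.null(model$scale)) Xc <- sweep(Xc, 2, model$scale, "/")
  sc <- Xc %*% model$rotation[, seq_len(k), drop = FALSE]
  attr(sc, "variant") <- meta_v
  attr(sc, "replica") <- meta_r
  sc
}

#' Rank variants by distance from the wild type in PC space
#'
#' Each variant's trajectories are averaged in projected space (by
#' linearity this equals projecting the mean feature row) and the
#' Euclidean distance of each variant mean from the wild-type mean is
#' computed in the first `k` components. Variants are sorted by
#' ascending distance, ties broken alphabetically by label.
#'
#' @param scores projection matrix from [project_pca()] with a
#'   `variant` attribute, or a plain matrix plus `variant` argument.
#' @param wild_type_label label of the wild-type variant.
#' @param variant optional per-row variant labels (overrides the
#'   attribute).
#' @param k number of components to use, default all columns of
#'   `scores`.
#' @return object of class `variant_ranking`: data.frame with columns
#'   `label`, `distance`, `rank`, plus the mean scores.
#' @export
rank_variants <- function(scores, wild_type_label, variant = NULL,
                          k = NULL) {
  if (is.null(variant)) variant <- attr(scores, "variant")
  if (is.null(variant)) stop("per-row variant labels required")
  scores <- unclass(scores)
  stopifnot(length(variant) == nrow(scores))
  if (is.null(k)) k <- ncol(scores)
  if (!wild_type_label %in% variant)
    stop("wild-type label '", wild_type_label, "' not found")
  sc <- scores[, seq_len(k), drop = FALSE]
  labs <- sort(unique(variant))
  means <- t(vapply(labs, function(v)
    colMeans(sc[variant == v, , drop = FALSE]), numeric(k)))
  wt <- means[wild_type_label, ]
  d <- sqrt(rowSums(sweep(means, 2, wt)^2))
  ord <- order(d, labs)
  out <- data.frame(label = labs[ord], distance = d[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  out <- cbind(out, means[ord, , drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("variant_ranking", "data.frame")
  out
}
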