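## small helper: occupancy_set-like array from a residue x 5 matrix
occ_set_of <- function(m, variant, replicas = 1) {
  arr <- array(rep(m, replicas), dim = c(nrow(m), 5, replicas),
               dimnames = list(residue = rownames(m),
                               class = RAMA_CLASSES,
                               replica = seq_len(replicas)))
  structure(arr, class = "occupancy_set", variant = variant,
            n_frames = rep(100L, replicas))
}

test_that("feature construction collapses five classes to three", {
  m <- matrix(c(0.2, 0.1, 0.3, 0.3, 0.1), 1, 5,
              dimnames = list("2", RAMA_CLASSES))
  X <- build_features(occ_set_of(m, "v1"))
  expect_equal(unname(unclass(X)[1, ]), c(0.2, 0.6, 0.2))
  expect_equal(colnames(X), c("r2_alphaR", "r2_betaPPII",
                              "r2_unstructured"))
  ## per-residue triplets sum to 1 on real generated data
  ens <- generate_ensemble(WT_SEQ, n_replicas = 3, n_frames = 100,
                           seed = 17)
  X2 <- build_features(occupancy(ens$dihedrals))
  expect_equal(dim(unclass(X2)), c(3, 39))  # 13 interior residues x 3
  sums <- sapply(seq_len(13), function(r)
    rowSums(unclass(X2)[, (3 * r - 2):(3 * r), drop = FALSE]))
  expect_lt(max(abs(sums - 1)), 1e-12)
  ## grouping must partition the five classes
  expect_error(build_features(occupancy(ens$dihedrals),
                              grouping = list(a = "alphaR")),
               "partition")
})

test_that("PCA matches a dense eigensolver oracle", {
  set.seed(33)
  X <- matrix(rnorm(60), 10, 6)
  model <- fit_pca(X)
  ev <- eigen(cov(X), symmetric = TRUE)$values
  expect_equal(model$sdev^2, ev[seq_along(model$sdev)],
               tolerance = 1e-9)
  expect_equal(model$var_explained, ev / sum(ev), tolerance = 1e-9)
  ## orthonormal components
  G <- crossprod(model$rotation)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  ## explained variance non-increasing, sums to <= 1
  expect_true(all(diff(model$var_explained) <= 1e-12))
  expect_lte(sum(model$var_explained), 1 + 1e-8)
})

test_that("PCA handles degenerate inputs by contract", {
  ## two distinct rows: PC1 explains everything
  X <- rbind(c(1, 0, 0), c(0, 1, 0))
  m <- fit_pca(X)
  expect_equal(m$var_explained[1], 1)
  ## duplicated rows give the same model as the original rows
  set.seed(2)
  Y <- matrix(rnorm(30), 5, 6)
  m1 <- fit_pca(Y)
  m2 <- fit_pca(Y[rep(1:5, 3), ])
  expect_equal(abs(m1$rotation[, 1:4]), abs(m2$rotation[, 1:4]),
               tolerance = 1e-8)
  expect_equal(m1$var_explained[1:4], m2$var_explained[1:4],
               tolerance = 1e-8)
  ## identical rows: zero variance, all-zero projection, no error
  Z <- matrix(1, 4, 3)
  mz <- fit_pca(Z)
  expect_equal(mz$var_explained, rep(0, length(mz$var_explained)))
  expect_equal(unname(project_pca(mz, Z, k = 2)),
               matrix(0, 4, 2), ignore_attr = TRUE)
  expect_error(fit_pca(Z[1, , drop = FALSE]), "2 rows")
})

test_that("projection is centered, linear, and lossless at full rank", {
  set.seed(44)
  X <- matrix(rnorm(48), 8, 6)
  m <- fit_pca(X)
  ## column-mean vector projects to the origin
  expect_equal(unname(project_pca(m, colMeans(X), k = 2)),
               matrix(0, 1, 2), tolerance = 1e-12)
  ## full-rank reconstruction
  k <- length(m$sdev)
  S <- project_pca(m, X, k = k)
  Xrec <- sweep(unclass(S) %*% t(m$rotation[, 1:k]), 2, m$center, "+")
  expect_lt(max(abs(Xrec - X)), 1e-9)
  ## mean of projections equals projection of the mean row
  expect_equal(colMeans(unclass(project_pca(m, X, k = 2))),
               as.vector(project_pca(m, colMeans(X), k = 2)),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(project_pca(m, X[, 1:3], k = 2), "mismatch")
})

test_that("variant ranking distances behave by contract", {
  set.seed(55)
  X <- matrix(rnorm(40), 10, 4)
  variant <- rep(c("wt", "v1", "v1", "v2", "v2"), 2)
  m <- fit_pca(X)
  sc <- project_pca(m, X, k = 2)
  attr(sc, "variant") <- variant
  rk <- rank_variants(sc, "wt")
  expect_equal(rk$distance[rk$label == "wt"], 0)
  expect_true(all(rk$distance >= 0))
  expect_equal(sort(rk$rank), 1:3)
  ## distances invariant to component sign flips
  m2 <- m; m2$rotation <- -m2$rotation
  sc2 <- project_pca(m2, X, k = 2)
  attr(sc2, "variant") <- variant
  rk2 <- rank_variants(sc2, "wt")
  expect_equal(rk2$distance[order(rk2$label)],
               rk$distance[order(rk$label)], tolerance = 1e-10)
  ## a variant whose rows copy the wild type's ties at distance 0
  X2 <- rbind(X[1:2, ], X[1:2, ])
  sc3 <- project_pca(m, X2, k = 2)
  attr(sc3, "variant") <- c("wt", "wt", "twin", "twin")
  rk3 <- rank_variants(sc3, "wt")
  expect_equal(max(rk3$distance), 0)
  expect_equal(rk3$label, c("twin", "wt"))  # alphabetical tie-break
  expect_error(rank_variants(sc, "nope"), "not found")
})

test_that("graded propensity shifts rank in shift order", {
  shifts <- c(v_small = 0.05, v_mid = 0.10, v_big = 0.20)
  wt_prof <- default_propensity_profile(WT_SEQ)
  occ_sets <- list()
  ens <- generate_ensemble(WT_SEQ, wt_prof, n_replicas = 4,
                           n_frames = 400, seed = 700)
  occ_sets[["wt"]] <- occupancy(ens$dihedrals)
  attr(occ_sets[["wt"]], "variant") <- "wt"
  for (v in names(shifts)) {
    p <- wt_prof
    for (r in 2:4) p <- shift_propensity(p, r, "alphaR", shifts[[v]])
    e <- generate_ensemble(WT_SEQ, p, n_replicas = 4, n_frames = 400,
                           seed = 700 + match(v, names(shifts)) * 37)
    occ_sets[[v]] <- occupancy(e$dihedrals)
    attr(occ_sets[[v]], "variant") <- v
  }
  X <- build_features(occ_sets)
  m <- fit_pca(X)
  sc <- project_pca(m, X, k = 2)
  rk <- rank_variants(sc, "wt")
  expect_equal(rk$label, c("wt", "v_small", "v_mid", "v_big"))
  ## Spearman correlation of injected magnitude and distance is exactly 1
  d <- rk$distance[match(names(shifts), rk$label)]
  expect_equal(cor(d, shifts, method = "spearman"), 1)
})
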