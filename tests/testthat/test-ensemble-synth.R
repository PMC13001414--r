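test_that("sampling is deterministic under a fixed seed", {
  prof <- default_propensity_profile(WT_SEQ)
  a <- sample_dihedrals(prof, n_frames = 5, seed = 7, sequence = WT_SEQ)
  b <- sample_dihedrals(prof, n_frames = 5, seed = 7, sequence = WT_SEQ)
  expect_identical(a, b)
  c <- sample_dihedrals(prof, n_frames = 5, seed = 8, sequence = WT_SEQ)
  expect_false(identical(a$phi, c$phi))
  ## full ensembles too
  e1 <- generate_ensemble(WT_SEQ, n_replicas = 2, n_frames = 5, seed = 3)
  e2 <- generate_ensemble(WT_SEQ, n_replicas = 2, n_frames = 5, seed = 3)
  expect_identical(e1$dihedrals, e2$dihedrals)
})

test_that("generator validates its configuration", {
  prof <- default_propensity_profile(WT_SEQ)
  expect_error(sample_dihedrals(prof, n_frames = 0, seed = 1), "positive")
  basins <- default_basins()
  basins$beta <- NULL
  expect_error(sample_dihedrals(prof, basins = basins, n_frames = 5,
                                seed = 1), "beta")
  expect_error(propensity_profile(matrix(c(0.5, 0.5, 0, 0, 0.1), 1, 5)),
               "sum to 1")
  expect_error(propensity_profile(matrix(c(-0.1, 1.1, 0, 0, 0), 1, 5)),
               "negative")
  expect_error(generate_ensemble(WT_SEQ, n_replicas = 0, n_frames = 5,
                                 seed = 1), "n_replicas")
})

test_that("angles are wrapped and frames counted per replica", {
  ens <- generate_ensemble(WT_SEQ, n_replicas = 16, n_frames = 100,
                           seed = 2)
  d <- ens$dihedrals
  expect_equal(nrow(d$phi), 1600)
  expect_equal(sort(unique(d$replica)), 1:16)
  expect_true(all(d$phi > -180 & d$phi <= 180))
  expect_true(all(d$psi > -180 & d$psi <= 180))
  expect_equal(d$residues, 2:14)
})

test_that("built chains satisfy peptide geometry bounds", {
  ens <- tiny_ensemble(1, 5, seed = 31)
  g <- ideal_geometry()
  for (cf in ens$conformations) {
    ca <- cf$xyz[cf$atom == "CA", ]
    dca <- sqrt(rowSums(diff(ca)^2))
    expect_true(all(dca >= 2.7 & dca <= 4.1))
    ## bond lengths at the ideal values used to build the chain
    for (i in 2:max(cf$resno)) {
      n_i <- cf$xyz[cf$atom == "N" & cf$resno == i, ]
      ca_i <- cf$xyz[cf$atom == "CA" & cf$resno == i, ]
      c_prev <- cf$xyz[cf$atom == "C" & cf$resno == i - 1, ]
      expect_equal(sqrt(sum((n_i - c_prev)^2)), g$b_c_n,
                   tolerance = 0.05)
      expect_equal(sqrt(sum((ca_i - n_i)^2)), g$b_n_ca,
                   tolerance = 0.05)
    }
  }
})

test_that("trans chains reproduce the closed-form CA-CA virtual bond", {
  ## with omega = 180 the CA(i), C(i), N(i+1), CA(i+1) atoms are
  ## coplanar; the virtual bond follows from two law-of-cosines steps
  ## in that plane. Build the oracle by explicit 2-D trigonometry.
  g <- ideal_geometry()
  th1 <- g$a_ca_c_n * pi / 180
  th2 <- g$a_c_n_ca * pi / 180
  ca1 <- c(0, 0)
  cc <- c(g$b_ca_c, 0)
  n <- cc + g$b_c_n * c(-cos(th1), sin(th1))
  u <- (cc - n) / sqrt(sum((cc - n)^2))
  rot <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  ## two in-plane placements satisfy the N bond angle; trans (omega =
  ## 180) is the one with CA2 across the C-N axis from CA1, i.e. farther
  cand <- lapply(c(th2, -th2), function(a)
    n + g$b_n_ca * as.vector(rot(a) %*% u))
  d <- vapply(cand, function(p) sqrt(sum((p - ca1)^2)), 0)
  oracle <- max(d)
  expect_equal(oracle, 3.80, tolerance = 0.02)
  ## any dihedrals, trans peptide: every consecutive CA-CA distance
  ## equals that oracle
  set.seed(12)
  phi <- c(NA, runif(13, -180, 180), runif(1, -180, 180))
  psi <- c(runif(14, -180, 180), NA)
  cf <- build_backbone(phi, psi, WT_SEQ)
  ca <- cf$xyz[cf$atom == "CA", ]
  expect_equal(sqrt(rowSums(diff(ca)^2)), rep(oracle, 14),
               tolerance = 1e-9)
})

test_that("dihedral round trip through coordinates is exact to 1e-3 deg", {
  set.seed(4)
  for (rep in 1:3) {
    phi <- c(NA, runif(14, -180, 180))
    psi <- c(runif(14, -180, 180), NA)
    cf <- build_backbone(phi, psi, WT_SEQ)
    d <- conformation_dihedrals(cf)
    expect_equal(d$phi, phi[2:14], tolerance = 1e-3)
    expect_equal(d$psi, psi[2:14], tolerance = 1e-3)
  }
  expect_error(build_backbone(c(NA, NaN, rep(0, 13)), rep(0, 15), WT_SEQ),
               "non-finite")
})

test_that("identical dihedrals give congruent conformations", {
  set.seed(9)
  phi <- c(NA, runif(14, -180, 180))
  psi <- c(runif(14, -180, 180), NA)
  a <- build_backbone(phi, psi, WT_SEQ)
  b <- build_backbone(phi, psi, WT_SEQ)
  ## internal coordinates determine shape up to rigid motion: all
  ## pairwise interatomic distances agree
  da <- dist(a$xyz); db <- dist(b$xyz)
  expect_lt(max(abs(da - db)), 1e-6)
})

test_that("replica seed permutation leaves ensemble statistics unchanged", {
  prof <- default_propensity_profile(WT_SEQ)
  occ_mean <- function(first_seed) {
    series <- lapply(0:3, function(i)
      sample_dihedrals(prof, n_frames = 500, seed = first_seed + i,
                       sequence = WT_SEQ, replica = i + 1))
    occ <- lapply(series, function(s) unclass(occupancy(s))[, , 1])
    Reduce(`+`, occ) / length(occ)
  }
  ## same seeds in different order = same replica set, identical mean;
  ## disjoint seeds differ only by Monte-Carlo error
  m1 <- occ_mean(100)
  m2 <- occ_mean(104)
  expect_lt(max(abs(m1 - m2)), 0.08)  # ~4 sigma binomial at n = 2000
})

test_that("injected propensity shifts are recovered in deviations", {
  wt_prof <- default_propensity_profile(WT_SEQ)
  v_prof <- shift_propensity(wt_prof, residue = 2, class = "alphaR",
                             shift = 0.15)
  expect_equal(unclass(v_prof)[1, "alphaR"],
               unclass(wt_prof)[1, "alphaR"] + 0.15, ignore_attr = TRUE)
  expect_equal(unname(rowSums(unclass(v_prof))), rep(1, 13))
  wt <- generate_ensemble(WT_SEQ, wt_prof, n_replicas = 4,
                          n_frames = 800, seed = 50)
  vv <- generate_ensemble(WT_SEQ, v_prof, n_replicas = 4,
                          n_frames = 800, seed = 150)
  dev <- deviation_profile(average_profiles(occupancy(vv$dihedrals)),
                           average_profiles(occupancy(wt$dihedrals)))
  expect_lt(abs(dev$delta["2", "alphaR"] - 0.15), 0.04)
  expect_lt(max(abs(rowSums(dev$delta))), 1e-12)
})
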