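KBT310 <- 0.0019872041 * 310

test_that("the helicity CV is a bounded membership average", {
  cv <- helicity_cv()
  ## all residues at the reference point
  expect_equal(helicity(rep(-60, 13), rep(-45, 13), cv), 1.0)
  ## all residues >= 4 sigma away in both angles
  expect_lt(helicity(rep(100, 13), rep(100, 13), cv), 0.001)
  ## half at center, half far away
  expect_equal(helicity(c(rep(-60, 5), rep(120, 5)),
                        c(rep(-45, 5), rep(140, 5)), cv),
               0.5, tolerance = 0.001)
  ## matrix input gives one value per frame, all within [0, 1]
  set.seed(3)
  phi <- matrix(runif(40, -180, 180), 4)
  psi <- matrix(runif(40, -180, 180), 4)
  h <- helicity(phi, psi, cv)
  expect_length(h, 4)
  expect_true(all(h >= 0 & h <= 1))
  ## angle wrapping: -60 and 300 are the same angle
  expect_equal(helicity(300, -45, cv), 1.0)
})

test_that("bump >= 0.5 implies an alphaR classification (default params)", {
  set.seed(8)
  phi <- runif(4000, -180, 180)
  psi <- runif(4000, -180, 180)
  h <- exp(-angle_diff(phi, -60)^2 / (2 * 30^2)) *
    exp(-angle_diff(psi, -45)^2 / (2 * 30^2))
  sel <- h >= 0.5
  expect_gt(sum(sel), 50)
  expect_true(all(classify_rama(phi[sel], psi[sel]) == "alphaR"))
})

test_that("well-tempered deposition damps hill heights", {
  tr <- wtm_trace(height = 0.5, width = 0.05, gamma = 10,
                  temperature = 310)
  tr <- deposit_hill(tr, 0.5)
  expect_equal(tr$hills$height[1], 0.5)  # exp(0) = 1
  for (i in 1:10) tr <- deposit_hill(tr, 0.5)
  expect_true(all(diff(tr$hills$height) < 0))
  ## gamma -> Inf limit: ordinary metadynamics, constant heights
  tr2 <- wtm_trace(height = 0.5, width = 0.05, gamma = 1e9)
  for (i in 1:5) tr2 <- deposit_hill(tr2, 0.5)
  expect_equal(tr2$hills$height, rep(0.5, 5), tolerance = 1e-6)
  expect_error(wtm_trace(gamma = 1), "gamma")
  ## cumulative bias at the deposition point grows sub-linearly
  v <- vapply(seq_len(nrow(tr$hills)), function(k)
    bias_potential(tr, 0.5, fraction = k / nrow(tr$hills)), 0)
  expect_true(all(diff(v, lag = 2) < 2 * v[2] - 1e-12))
})

test_that("bias potential equals the direct Gaussian summation", {
  set.seed(14)
  tr <- wtm_trace(height = 0.3, width = 0.07)
  tr$hills <- data.frame(time = 1:20, center = runif(20),
                         width = 0.07, height = runif(20, 0.1, 0.3))
  expect_equal(bias_potential(tr, numeric(0)), numeric(0))
  s <- seq(0, 1, length.out = 31)
  oracle <- sapply(s, function(x)
    sum(tr$hills$height * exp(-(x - tr$hills$center)^2 / (2 * 0.07^2))))
  expect_equal(bias_potential(tr, s), oracle, tolerance = 1e-12)
  ## empty trace is zero everywhere; single hill peaks at its height
  expect_equal(bias_potential(wtm_trace(), s), rep(0, 31))
  tr1 <- deposit_hill(wtm_trace(height = 0.4), 0.3)
  expect_equal(bias_potential(tr1, 0.3), 0.4)
})

test_that("unbiased Langevin sampling matches Boltzmann statistics", {
  ## flat landscape: uniform occupation (thinned to near-independent
  ## samples; the raw trajectory is autocorrelated)
  run <- langevin_run(function(s) 0 * s, steps = 100000,
                      diffusion = 5e-2, seed = 5)
  thin <- run$s[seq(400, length(run$s), by = 400)]
  counts <- table(cut(thin, seq(0, 1, by = 0.2)))
  expect_gt(chisq.test(counts)$p.value, 1e-3)
  expect_equal(mean(run$s), 0.5, tolerance = 0.1)
  ## determinism
  run2 <- langevin_run(function(s) 0 * s, steps = 1000, seed = 5)
  run3 <- langevin_run(function(s) 0 * s, steps = 1000, seed = 5)
  expect_identical(run2$s, run3$s)
  ## steep single well: trajectory mean matches the Boltzmann average
  U <- function(s) 40 * (s - 0.6)^2
  run4 <- langevin_run(U, steps = 60000, diffusion = 1e-2, seed = 6)
  kBT <- run4$kBT
  z <- integrate(function(s) exp(-U(s) / kBT), 0, 1)$value
  s_bar <- integrate(function(s) s * exp(-U(s) / kBT) / z, 0, 1)$value
  expect_equal(mean(run4$s), s_bar, tolerance = 0.01)
})

test_that("PMF reconstruction is a scaled min-shifted bias image", {
  ## hill-order permutation leaves the PMF unchanged
  set.seed(21)
  tr <- wtm_trace(height = 0.2, width = 0.05)
  tr$hills <- data.frame(time = 1:30, center = runif(30), width = 0.05,
                         height = runif(30, 0.05, 0.2))
  tr2 <- tr
  tr2$hills <- tr$hills[sample(30), ]
  g <- seq(0, 1, length.out = 101)
  expect_equal(reconstruct_pmf(tr, g)$F, reconstruct_pmf(tr2, g)$F,
               tolerance = 1e-12)
  expect_equal(min(reconstruct_pmf(tr, g)$F), 0)
  ## prefactor gamma/(gamma-1) against the definition
  v <- bias_potential(tr, g)
  expect_equal(reconstruct_pmf(tr, g)$F, -10 / 9 * v - min(-10 / 9 * v))
  expect_error(reconstruct_pmf(wtm_trace(), g), "no hills")
  ## a long run on a flat landscape reconstructs a flat PMF
  flat <- langevin_run(function(s) 0 * s, steps = 100000,
                       diffusion = 1e-2, seed = 9,
                       metad = list(height = 0.1, width = 0.05,
                                    gamma = 10, stride = 50))
  pmf <- reconstruct_pmf(flat$trace, g)
  ## residual roughness stays below kBT, far under any landscape feature
  expect_lt(diff(range(pmf$F[g > 0.05 & g < 0.95])), 1.0 * KBT310)
})

test_that("convergence diagnostics report aligned RMS deviations", {
  set.seed(31)
  tr <- wtm_trace(height = 0.2, width = 0.05)
  tr$hills <- data.frame(time = 1:40, center = runif(40), width = 0.05,
                         height = runif(40, 0.05, 0.2))
  g <- seq(0, 1, length.out = 101)
  ## self-comparison: single fraction 1.0 has zero RMS and converges
  cs1 <- convergence_series(tr, g, fractions = 1)
  expect_equal(unname(cs1$rms), 0)
  expect_true(cs1$converged)
  cs <- convergence_series(tr, g)
  expect_length(cs$rms, 4)
  expect_equal(unname(cs$rms[4]), 0)
  expect_true(all(cs$rms >= 0))
  expect_true(any(cs$window))
})

test_that("a converged double-well run recovers the quadrature free energy", {
  U <- double_well_potential()
  g <- seq(0, 1, length.out = 400)
  dF_true <- basin_delta_f(g, U(g), KBT310)
  run <- langevin_run(U, steps = 200000, diffusion = 1e-2, seed = 2,
                      metad = list(height = 0.1, width = 0.05,
                                   gamma = 10, stride = 50))
  pmf <- reconstruct_pmf(run$trace, g)
  dF_hat <- basin_delta_f(g, pmf$F, KBT310)
  expect_lt(abs(dF_hat - dF_true), 0.3 * KBT310)
})
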