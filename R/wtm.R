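#' Smooth helical-content collective variable
#'
#' A differentiable membership bump around the right-handed helical
#' Ramachandran center: per residue
#' `exp(-dphi^2/(2*s_phi^2)) * exp(-dpsi^2/(2*s_psi^2))` with wrapped
#' angle differences, averaged over interior residues, so the CV lies in
#' [0, 1]. With the default widths the 0.5 level set of the bump lies
#' inside the default alphaR region, so bump >= 0.5 implies an alphaR
#' classification.
#'
#' @param center alphaR reference (phi0, psi0) in degrees.
#' @param sigma bump widths (s_phi, s_psi) in degrees.
#' @return object of class `helicity_cv`.
#' @export
helicity_cv <- function(center = c(-60, -45), sigma = c(30, 30)) {
  stopifnot(length(center) == 2, length(sigma) == 2, all(sigma > 0))
  structure(list(center = center, sigma = sigma), class = "helicity_cv")
}

#' Evaluate the helical-content CV
#'
#' @param phi,psi dihedrals in degrees: vectors (one frame) or
#'   frames x residues matrices.
#' @param cv a `helicity_cv`.
#' @return CV value(s) in [0, 1]: a scalar for vector input, a per-frame
#'   vector for matrix input.
#' @export
helicity <- function(phi, psi, cv = helicity_cv()) {
  stopifnot(inherits(cv, "helicity_cv"))
  dphi <- angle_diff(phi, cv$center[1])
  dpsi <- angle_diff(psi, cv$center[2])
  bump <- exp(-dphi^2 / (2 * cv$sigma[1]^2)) *
    exp(-dpsi^2 / (2 * cv$sigma[2]^2))
  if (is.matrix(phi)) rowMeans(bump) else mean(bump)
}

#' Create an empty well-tempered metadynamics hill trace
#'
#' @param height nominal hill height (kcal/mol), default 0.5 (coarse
#'   schedule; the fine schedule uses 0.1).
#' @param width Gaussian hill width in CV units, default 0.05 (fine:
#'   0.01).
#' @param gamma well-tempered bias factor (> 1), default 10.
#' @param temperature system temperature in K, default 310.
#' @return object of class `hill_trace`: list with a `hills` data.frame
#'   (`time`, `center`, `width`, `height` = deposited height) and the
#'   schedule parameters.
#' @export
wtm_trace <- function(height = 0.5, width = 0.05, gamma = 10,
                      temperature = 310) {
  if (gamma <= 1) stop("bias factor gamma must be > 1")
  stopifnot(height > 0, width > 0, temperature > 0)
  structure(list(
    hills = data.frame(time = numeric(0), center = numeric(0),
                       width = numeric(0), height = numeric(0)),
    height = height, width = width, gamma = gamma,
    temperature = temperature
  ), class = "hill_trace")
}

#' @export
print.hill_trace <- function(x, ...) {
  cat(sprintf(
    "<hill_trace> %d hills (h = %g kcal/mol, w = %g, gamma = %g, T = %g K)\n",
    nrow(x$hills), x$height, x$width, x$gamma, x$temperature))
  invisible(x)
}

#' Accumulated bias potential of a hill trace
#'
#' Direct Gaussian summation `sum_j h_j exp(-(s - c_j)^2 / (2 w_j^2))`.
#'
#' @param trace a `hill_trace`.
#' @param s CV value(s).
#' @param fraction use only the first `ceiling(fraction * n)` hills.
#' @return bias energy (kcal/mol) at each `s`.
#' @export
bias_potential <- function(trace, s, fraction = 1) {
  stopifnot(inherits(trace, "hill_trace"))
  h <- trace$hills
  n_use <- ceiling(fraction * nrow(h))
  if (n_use == 0) return(rep(0, length(s)))
  h <- h[seq_len(n_use), , drop = FALSE]
  vapply(s, function(x)
    sum(h$height * exp(-(x - h$center)^2 / (2 * h$width^2))), 0)
}

#' Deposit one well-tempered hill
#'
#' Appends a Gaussian hill at `s_now` with deposited height
#' `h * exp(-V_bias(s_now) / (kB * dT))`, `dT = (gamma - 1) * T`:
#' heights decay where bias has accumulated, and in the `gamma -> Inf`
#' limit the rule reduces to ordinary metadynamics (constant height).
#'
#' @param trace a `hill_trace`.
#' @param s_now current CV value (finite).
#' @param time time index for the new hill (default: hill count + 1).
#' @return the updated `hill_trace`.
#' @export
deposit_hill <- function(trace, s_now, time = NULL) {
  stopifnot(inherits(trace, "hill_trace"), is.finite(s_now))
  dT <- (trace$gamma - 1) * trace$temperature
  v <- bias_potential(trace, s_now)
  h_dep <- trace$height * exp(-v / (KB_KCAL * dT))
  if (is.null(time)) time <- nrow(trace$hills) + 1
  trace$hills <- rbind(trace$hills,
                       data.frame(time = time, center = s_now,
                                  width = trace$width, height = h_dep))
  trace
}

## numeric derivative of a scalar function, central difference
num_grad <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

## reflect positions into [lo, hi]
reflect_into <- function(s, lo, hi) {
  span <- hi - lo
  s <- (s - lo) %% (2 * span)
  s <- ifelse(s > span, 2 * span - s, s)
  s + lo
}

#' Overdamped Langevin dynamics on a model landscape, with optional WTM
#'
#' Euler-Maruyama integration of
#' `ds = -(D / kBT) d(U + V_bias)/ds dt + sqrt(2 D dt) xi`, with
#' reflecting boundaries at the domain edges. When `metad` is supplied,
#' well-tempered hills are deposited every `stride` steps; the bias and
#' its gradient are accumulated on a uniform grid and interpolated, so
#' the cost per step is independent of the hill count.
#'
#' @param potential function `U(s)` in kcal/mol.
#' @param domain CV domain, default `c(0, 1)`.
#' @param steps number of integration steps.
#' @param dt time step.
#' @param diffusion diffusion coefficient D (CV units^2 / time).
#' @param temperature temperature in K.
#' @param seed RNG seed (same seed, same trajectory).
#' @param metad NULL for unbiased dynamics, else a list with `height`,
#'   `width`, `gamma` and `stride` (steps between depositions).
#' @param grid_n bias/force grid resolution, default 400.
#' @param s0 starting point, default domain midpoint.
#' @return list with `s` (trajectory, length `steps`), `trace` (a
#'   `hill_trace`, empty when unbiased), `domain`, `kBT`.
#' @export
langevin_run <- function(potential, domain = c(0, 1), steps = 200000,
                         dt = 0.05, diffusion = 2e-3, temperature = 310,
                         seed = 1, metad = NULL, grid_n = 400,
                         s0 = NULL) {
  stopifnot(dt > 0, diffusion > 0, temperature > 0, steps >= 1)
  kBT <- KB_KCAL * temperature
  lo <- domain[1]; hi <- domain[2]
  if (is.null(s0)) s0 <- (lo + hi) / 2
  sg <- seq(lo, hi, length.out = grid_n)
  dUg <- vapply(sg, function(x) num_grad(potential, x), 0)
  vb <- numeric(grid_n); dvb <- numeric(grid_n)
  use_metad <- !is.null(metad)
  if (use_metad) {
    trace <- wtm_trace(metad$height, metad$width, metad$gamma, temperature)
    stride <- metad$stride
    dT <- (metad$gamma - 1) * temperature
    n_hills <- floor(steps / stride)
    h_time <- numeric(n_hills); h_ctr <- numeric(n_hills)
    h_dep <- numeric(n_hills); nh <- 0L
    w2 <- metad$width^2
  } else {
    trace <- NULL
  }
  with_seed(seed, {
    noise <- stats::rnorm(steps, 0, sqrt(2 * diffusion * dt))
    s <- s0
    traj <- numeric(steps)
    mob <- diffusion / kBT * dt
    for (t in seq_len(steps)) {
      f <- -(interp_uniform(s, sg, dUg) +
             if (use_metad) interp_uniform(s, sg, dvb) else 0)
      s <- s + mob * f + noise[t]
      s <- reflect_into(s, lo, hi)
      if (!is.finite(s)) stop("trajectory diverged at step ", t)
      traj[t] <- s
      if (use_metad && t %% stride == 0L) {
        v_here <- interp_uniform(s, sg, vb)
        hd <- metad$height * exp(-v_here / (KB_KCAL * dT))
        g <- exp(-(sg - s)^2 / (2 * w2))
        vb <- vb + hd * g
        dvb <- dvb - hd * g * (sg - s) / w2
        nh <- nh + 1L
        h_time[nh] <- t; h_ctr[nh] <- s; h_dep[nh] <- hd
      }
    }
    if (use_metad) {
      trace$hills <- data.frame(time = h_time[seq_len(nh)],
                                center = h_ctr[seq_len(nh)],
                                width = metad$width,
                                height = h_dep[seq_len(nh)])
    }
    list(s = traj, trace = trace, domain = domain, kBT = kBT)
  })
}

#' Langevin dynamics on a 2-D landscape with bias on one coordinate only
#'
#' The deliberately "insufficient collective variable" scenario: the
#' system lives on `U(x, y)` but hills are deposited along `x` alone.
#' When `y` carries a slow orthogonal degree of freedom that reshapes
#' the `x` landscape, the reconstructed 1-D profile keeps evolving and
#' the convergence diagnostic flags the run.
#'
#' @param potential function `U(x, y)` in kcal/mol.
#' @param domain,steps,dt,diffusion,temperature,seed,metad,grid_n as in
#'   [langevin_run()]; both coordinates share the domain.
#' @param x0,y0 starting point, default domain midpoint / first well.
#' @return list with `x`, `y` trajectories and `trace`.
#' @export
langevin_run_2d <- function(potential, domain = c(0, 1), steps = 200000,
                            dt = 0.05, diffusion = 2e-3,
                            temperature = 310, seed = 1, metad,
                            grid_n = 400, x0 = NULL, y0 = NULL) {
  stopifnot(!is.null(metad))
  kBT <- KB_KCAL * temperature
  lo <- domain[1]; hi <- domain[2]
  if (is.null(x0)) x0 <- (lo + hi) / 2
  if (is.null(y0)) y0 <- lo + 0.25 * (hi - lo)
  sg <- seq(lo, hi, length.out = grid_n)
  vb <- numeric(grid_n); dvb <- numeric(grid_n)
  trace <- wtm_trace(metad$height, metad$width, metad$gamma, temperature)
  stride <- metad$stride
  dT <- (metad$gamma - 1) * temperature
  w2 <- metad$width^2
  n_hills <- floor(steps / stride)
  h_time <- numeric(n_hills); h_ctr <- numeric(n_hills)
  h_dep <- numeric(n_hills); nh <- 0L
  eps <- 1e-6
  with_seed(seed, {
    nx <- stats::rnorm(steps, 0, sqrt(2 * diffusion * dt))
    ny <- stats::rnorm(steps, 0, sqrt(2 * diffusion * dt))
    x <- x0; y <- y0
    xt <- numeric(steps); yt <- numeric(steps)
    mob <- diffusion / kBT * dt
    for (t in seq_len(steps)) {
      dUx <- (potential(x + eps, y) - potential(x - eps, y)) / (2 * eps)
      dUy <- (potential(x, y + eps) - potential(x, y - eps)) / (2 * eps)
      fx <- -(dUx + interp_uniform(x, sg, dvb))
      x <- reflect_into(x + mob * fx + nx[t], lo, hi)
      y <- reflect_into(y - mob * dUy + ny[t], lo, hi)
      xt[t] <- x; yt[t] <- y
      if (t %% stride == 0L) {
        hd <- metad$height *
          exp(-interp_uniform(x, sg, vb) / (KB_KCAL * dT))
        g <- exp(-(sg - x)^2 / (2 * w2))
        vb <- vb + hd * g
        dvb <- dvb - hd * g * (sg - x) / w2
        nh <- nh + 1L
        h_time[nh] <- t; h_ctr[nh] <- x; h_dep[nh] <- hd
      }
    }
    trace$hills <- data.frame(time = h_time[seq_len(nh)],
                              center = h_ctr[seq_len(nh)],
                              width = metad$width,
                              height = h_dep[seq_len(nh)])
    list(x = xt, y = yt, trace = trace, domain = domain, kBT = kBT)
  })
}

#' Reconstruct the PMF from an accumulated hill trace
#'
#' `F(s) = -((T + dT) / dT) * V_bias(s) + C` with
#' `dT = (gamma - 1) T` (so the prefactor is `gamma / (gamma - 1)`),
#' using only the first `ceiling(f * n)` hills, min-shifted to 0.
#'
#' @param trace a `hill_trace` with at least one hill in the truncation.
#' @param grid CV grid, default 400 points over [0, 1].
#' @param fraction trajectory fraction f in (0, 1].
#' @return object of class `pmf_profile`: data.frame (`s`, `F`) with
#'   attribute `fraction`.
#' @export
reconstruct_pmf <- function(trace, grid = seq(0, 1, length.out = 400),
                            fraction = 1) {
  stopifnot(inherits(trace, "hill_trace"),
            fraction > 0, fraction <= 1)
  n_use <- ceiling(fraction * nrow(trace$hills))
  if (n_use == 0) stop("no hills in the truncated trace")
  v <- bias_potential(trace, grid, fraction = fraction)
  f <- -trace$gamma / (trace$gamma - 1) * v
  f <- f - min(f)
  out <- data.frame(s = grid, F = f)
  attr(out, "fraction") <- fraction
  class(out) <- c("pmf_profile", "data.frame")
  out
}

#' Time-resolved convergence diagnostic for a WTM run
#'
#' Reconstructs the PMF at successive trajectory fractions, aligns each
#' profile to the final one by subtracting its mean over the
#' low-free-energy window `{s : F_final(s) < cutoff}`, and reports the
#' RMS deviation of each aligned profile from the final profile over
#' that window. The run is flagged as non-converged when the RMS of the
#' largest fraction below the final one still exceeds
#' `flag_threshold_kt * kBT` (late bias still reshaping the profile).
#'
#' @param trace a `hill_trace`.
#' @param grid CV grid.
#' @param fractions sorted trajectory fractions in (0, 1].
#' @param window_cutoff_kt low-free-energy window cutoff, in units of
#'   kBT above the minimum; default 3.
#' @param flag_threshold_kt non-convergence threshold in kBT; default
#'   0.5.
#' @return object of class `wtm_convergence`: list with `profiles` (one
#'   `pmf_profile` per fraction), `fractions`, `rms` (named vector,
#'   kcal/mol), `window` (logical grid mask), `converged`, `kBT`.
#' @export
convergence_series <- function(trace, grid = seq(0, 1, length.out = 400),
                               fractions = c(0.25, 0.5, 0.75, 1),
                               window_cutoff_kt = 3,
                               flag_threshold_kt = 0.5) {
  stopifnot(all(diff(fractions) > 0), all(fractions > 0),
            all(fractions <= 1))
  kBT <- KB_KCAL * trace$temperature
  profiles <- lapply(fractions, function(f)
    reconstruct_pmf(trace, grid, fraction = f))
  final <- profiles[[length(profiles)]]
  window <- final$F < window_cutoff_kt * kBT
  if (!any(window)) stop("empty low-free-energy window")
  f_fin <- final$F - mean(final$F[window])
  rms <- vapply(profiles, function(p) {
    f_al <- p$F - mean(p$F[window])
    sqrt(mean((f_al[window] - f_fin[window])^2))
  }, 0)
  names(rms) <- format(fractions)
  n <- length(fractions)
  last_rms <- if (n > 1) rms[n - 1] else 0
  structure(list(profiles = profiles, fractions = fractions, rms = rms,
                 window = window, last_rms = unname(last_rms),
                 converged = unname(last_rms) <= flag_threshold_kt * kBT,
                 kBT = kBT),
            class = "wtm_convergence")
}

#' @export
print.wtm_convergence <- function(x, ...) {
  cat("<wtm_convergence>",
      if (x$converged) "converged" else "NOT converged", "\n")
  cat("  RMS vs final (kcal/mol):",
      paste(sprintf("f=%s: %.3f", names(x$rms), x$rms), collapse = ", "),
      "\n")
  invisible(x)
}

#' Model free-energy landscapes for desk-scale WTM experiments
#'
#' `double_well_potential()` returns a quartic double well on [0, 1]
#' with wells near 0.25 and 0.75, barrier height `barrier` (kcal/mol) at
#' the midpoint and a linear `tilt` making the wells inequivalent.
#' `hidden_dof_potential()` returns a 2-D landscape whose second
#' coordinate is a slow double well coupled to the first: biasing only
#' the first coordinate is then an insufficient collective variable.
#'
#' @param barrier barrier height, kcal/mol.
#' @param tilt linear tilt, kcal/mol over the unit domain.
#' @param wells well positions.
#' @return a function `U(s)` (or `U(x, y)`).
#' @export
double_well_potential <- function(barrier = 2.5, tilt = 1.0,
                                  wells = c(0.25, 0.75)) {
  mid <- mean(wells)
  norm <- ((mid - wells[1]) * (mid - wells[2]))^2
  function(s) barrier * ((s - wells[1]) * (s - wells[2]))^2 / norm +
    tilt * s
}

#' @rdname double_well_potential
#' @param barrier_x,barrier_y barrier heights of the fast (biased) and
#'   slow (hidden) coordinates, kcal/mol.
#' @param coupling coupling strength, kcal/mol; the hidden coordinate's
#'   basin flips the tilt of the biased coordinate.
#' @export
hidden_dof_potential <- function(barrier_x = 2.0, barrier_y = 5.3,
                                 coupling = 16.0) {
  ux <- double_well_potential(barrier_x, tilt = 0)
  uy <- double_well_potential(barrier_y, tilt = 0)
  function(x, y) ux(x) + uy(y) + coupling * (y - 0.5) * (x - 0.5)
}

#' Basin free-energy difference of a tabulated profile
#'
#' `-kBT * log(Z_right / Z_left)` with the partition functions computed
#' by trapezoidal Boltzmann integration over the two sides of `split`.
#' Applicable both to an analytic potential tabulated on a grid and to
#' a reconstructed PMF, which makes converged reconstructions directly
#' comparable to quadrature on the true landscape.
#'
#' @param s grid (ascending).
#' @param f energy values on the grid (kcal/mol).
#' @param kBT thermal energy (kcal/mol).
#' @param split basin boundary, default 0.5.
#' @return free-energy difference right minus left, kcal/mol.
#' @export
basin_delta_f <- function(s, f, kBT, split = 0.5) {
  stopifnot(length(s) == length(f), all(diff(s) > 0))
  w <- exp(-(f - min(f)) / kBT)
  trap <- function(x, y)
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  left <- s <= split
  -kBT * log(trap(s[!left], w[!left]) / trap(s[left], w[left]))
}
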