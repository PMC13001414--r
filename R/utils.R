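#' @keywords internal
"_PACKAGE"

## Boltzmann constant, kcal/(mol K) -- NAMD/colvars energy convention
KB_KCAL <- 0.0019872041

## The five Ramachandran classes, in canonical column order.
RAMA_CLASSES <- c("alphaR", "alphaL", "beta", "PPII", "unassigned")

#' Wrap angles into the interval (-180, 180]
#'
#' All dihedral arithmetic in the package uses degrees wrapped into
#' `(-180, 180]`; -180 itself maps to +180 so that the interval is
#' half-open on the left.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped into (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(-180, 180, 270, -190))
wrap_angle <- function(x) {
  180 - ((180 - x) %% 360)
}

## Smallest wrapped difference a - b on the circle, in (-180, 180].
angle_diff <- function(a, b) {
  wrap_angle(a - b)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Linear interpolation of tabulated (xg, yg) at x; xg must be a uniform
## ascending grid. Clamped at the edges. Used by the Langevin/WTM engine.
interp_uniform <- function(x, xg, yg) {
  n <- length(xg)
  h <- xg[2] - xg[1]
  i <- floor((x - xg[1]) / h) + 1
  i <- pmin(pmax(i, 1L), n - 1L)
  w <- (x - xg[i]) / h
  w <- pmin(pmax(w, 0), 1)
  yg[i] * (1 - w) + yg[i + 1] * w
}

## 3-vector cross product.
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v * v))
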