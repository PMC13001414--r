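## Shared fixtures built in code.

WT_SEQ <- "MEVQLGLGRVYPRPP"

## a small deterministic ensemble with coordinates
tiny_ensemble <- function(n_replicas = 2, n_frames = 4, seed = 11,
                          coords = TRUE) {
  generate_ensemble(WT_SEQ, n_replicas = n_replicas, n_frames = n_frames,
                    seed = seed, coords = coords)
}

## a random rigid motion (rotation + translation) applied to coordinates
random_rigid <- function(xyz, seed) {
  set.seed(seed)
  a <- stats::rnorm(3)
  theta <- stats::runif(1, 0, 2 * pi)
  u <- a / sqrt(sum(a^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
  sweep(xyz %*% R, 2, stats::rnorm(3, sd = 5), "+")
}

## independent acos-based dihedral oracle (distinct formula from the
## package's atan2 implementation): unsigned angle from the two plane
## normals, sign from the triple product of n1 with b3.
dihedral_oracle <- function(p1, p2, p3, p4) {
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  ct <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(pmin(pmax(ct, -1), 1)) * 180 / pi
  if (sum(n1 * b3) < 0) -ang else ang
}
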