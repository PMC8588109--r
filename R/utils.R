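## Internal geometry / numerics helpers.

cross3 <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) abort("cannot normalise a zero vector")
  v / n
}

## Rotation matrix: rotate by angle (rad) about unit axis (Rodrigues).
rot_about <- function(axis, angle) {
  u <- unit3(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

## Uniform random unit vectors (n x 3).
runif_sphere <- function(n) {
  z <- stats::rnorm(n * 3)
  m <- matrix(z, ncol = 3)
  m / sqrt(rowSums(m^2))
}

## Uniform random points in a ball of radius R (n x 3).
runif_ball <- function(n, R, r_min = 0) {
  u <- stats::runif(n)
  r <- (r_min^3 + u * (R^3 - r_min^3))^(1 / 3)
  runif_sphere(n) * r
}

## Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

## Squared distances between two coordinate matrices (na x 3, nb x 3) -> na x nb.
cross_dist2 <- function(a, b) {
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  d2
}

coords_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}
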