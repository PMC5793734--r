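## Low-level 3-D geometry helpers shared by the feature calculators and the
## synthetic-structure generators.  All coordinates are in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector has no direction")
  v / n
}

## Dihedral angle a-b-c-d in degrees, in (-180, 180].
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- c(
    b1[2] * b2[3] - b1[3] * b2[2],
    b1[3] * b2[1] - b1[1] * b2[3],
    b1[1] * b2[2] - b1[2] * b2[1]
  )
  n2 <- c(
    b2[2] * b3[3] - b2[3] * b3[2],
    b2[3] * b3[1] - b2[1] * b3[3],
    b2[1] * b3[2] - b2[2] * b3[1]
  )
  m1 <- c(
    n1[2] * unit(b2)[3] - n1[3] * unit(b2)[2],
    n1[3] * unit(b2)[1] - n1[1] * unit(b2)[3],
    n1[1] * unit(b2)[2] - n1[2] * unit(b2)[1]
  )
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

## Bond angle at b (a-b-c) in degrees.
bond_angle <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

## Natural-extension reference frame (NeRF) atom placement: position a new
## atom d with |c-d| = bond, angle(b,c,d) = angle and dihedral(a,b,c,d) =
## torsion (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  bc <- unit(c - b)
  ab <- b - a
  n <- unit(c(
    ab[2] * bc[3] - ab[3] * bc[2],
    ab[3] * bc[1] - ab[1] * bc[3],
    ab[1] * bc[2] - ab[2] * bc[1]
  ))
  m <- c(
    n[2] * bc[3] - n[3] * bc[2],
    n[3] * bc[1] - n[1] * bc[3],
    n[1] * bc[2] - n[2] * bc[1]
  )
  frame <- cbind(bc, m, n)
  c + as.vector(frame %*% d_local)
}

## Deterministic quasi-uniform points on the unit sphere (golden-section
## spiral).  Used by the solvent-accessibility and depth calculators so all
## geometric outputs are bit-reproducible.
sphere_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- golden * (i - 0.5)
  cbind(x = r * cos(theta), y = r * sin(theta), z = z)
}

## Squared-distance matrix between two coordinate matrices (rows = points).
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * (a %*% t(b))
}

min_dist <- function(a, b) {
  sqrt(max(0, min(cross_dist2(a, b))))
}
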