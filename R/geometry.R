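# Internal 3D geometry helpers shared by the fixture generator, the trimming
# module and the superposition engine. All coordinates are Angstrom, all
# angles degrees unless noted.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Dihedral angle of four points
#'
#' Signed torsion angle about the b-c axis, using the standard
#' atan2(cross, dot) formulation (numerically stable near 0 and 180 degrees).
#'
#' @param a,b,c,d numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  # IUPAC sign convention (clockwise positive viewed from b towards c)
  ang <- -rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# Natural extension reference frame (NeRF) atom placement: position atom D
# given the three preceding atoms A-B-C, the C-D bond length, the B-C-D bond
# angle and the A-B-C-D torsion. Used by the backbone builder.
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  d2 <- c(-bond * cos(th),
          bond * sin(th) * cos(ph),
          bond * sin(th) * sin(ph))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cbind(bc, cross3(n, bc), n)
  as.vector(m %*% d2) + c
}

# Minimum inter-point distance between two coordinate matrices (n x 3, m x 3).
# Vectorised squared-distance expansion; exact, no cutoffs.
min_pair_dist <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  sqrt(max(min(d2), 0))
}

# Uniform random rotation matrix (via QR of a Gaussian matrix, sign-fixed,
# reflection corrected). Deterministic under set.seed.
random_rotation <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Apply a rigid transform y = x R^T + t to an n x 3 coordinate matrix.
apply_rigid <- function(x, rotation, translation) {
  sweep(as.matrix(x) %*% t(rotation), 2, translation, "+")
}
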