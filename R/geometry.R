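# Crypt surface geometry ----------------------------------------------------
#
# The crypt is a hemisphere of radius R (the niche, z <= 0, centred at the
# origin with its pole at z = -R) smoothly joined to a cylinder of radius R
# and height H (0 <= z <= H); the crypt mouth is the circle z = H.  Cells
# are point agents constrained to this surface.

#' Project points onto the crypt surface
#'
#' Radial projection: points with z > 0 are scaled onto the cylinder wall
#' (z preserved, capped at the mouth); points with z <= 0 are scaled onto
#' the sphere of radius R.  Projection is idempotent up to floating-point
#' tolerance.
#'
#' @param xyz Numeric matrix (n x 3) of positions.
#' @param geom Geometry section of the configuration.
#' @return Matrix of projected positions.
#' @export
surface_project <- function(xyz, geom) {
  R <- geom$radius
  x <- xyz[, 1L]; y <- xyz[, 2L]; z <- xyz[, 3L]
  cyl <- z > 0
  rho <- sqrt(x * x + y * y)
  # degenerate points on the axis get an arbitrary fixed azimuth
  bad <- rho < 1e-12 & cyl
  x[bad] <- 1e-6; rho[bad] <- sqrt(x[bad]^2 + y[bad]^2)
  f <- ifelse(cyl, R / rho, 1)
  x2 <- x * f; y2 <- y * f; z2 <- pmin(z, geom$height)
  sph <- !cyl
  if (any(sph)) {
    nrm <- sqrt(x[sph]^2 + y[sph]^2 + z[sph]^2)
    nrm[nrm < 1e-12] <- 1e-12
    g <- R / nrm
    x2[sph] <- x[sph] * g; y2[sph] <- y[sph] * g; z2[sph] <- z[sph] * g
  }
  cbind(x2, y2, z2, deparse.level = 0L)
}

#' Surface constraint residual
#'
#' Distance of each point from the crypt surface (0 on the surface).
#'
#' @inheritParams surface_project
#' @return Numeric vector of residuals.
#' @export
surface_residual <- function(xyz, geom) {
  p <- surface_project(xyz, geom)
  sqrt(rowSums((xyz - p)^2))
}

#' Longitudinal coordinates on the crypt-villus axis
#'
#' For each position returns the polar angle `theta` (measured from the
#' crypt base pole; 0 at the bottom of the niche, pi/2 at the hemisphere
#' rim, constant above it) and the longitudinal arc length `s` from the
#' base (`R * theta` in the cap, `R * pi/2 + z` on the cylinder), plus `z`.
#' Both `theta` and `s` increase towards the villus and are continuous
#' across the cap-cylinder junction.
#'
#' @inheritParams surface_project
#' @return Data frame with columns `z`, `theta`, `s`.
#' @export
surface_coords <- function(xyz, geom) {
  R <- geom$radius
  z <- xyz[, 3L]
  theta <- ifelse(z > 0, pi / 2, acos(pmin(1, pmax(-1, -z / R))))
  s <- ifelse(z > 0, R * pi / 2 + z, R * theta)
  data.frame(z = z, theta = theta, s = s)
}

#' Is a position inside the hemispherical niche?
#'
#' @inheritParams surface_project
#' @return Logical vector (`z <= 0`).
#' @export
in_niche <- function(xyz, geom) xyz[, 3L] <= 0

# Random unit tangent vectors to the surface at given positions.
# Used for division placement; consumes one RNG draw (angle) per row.
surface_tangent <- function(xyz, geom) {
  n <- nrow(xyz)
  ang <- stats::runif(n, 0, 2 * pi)
  R <- geom$radius
  out <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    p <- xyz[i, ]
    nrml <- if (p[3L] > 0) c(p[1L], p[2L], 0) else p
    nn <- sqrt(sum(nrml^2)); if (nn < 1e-12) nrml <- c(0, 0, -1) else nrml <- nrml / nn
    # orthonormal tangent basis
    a <- if (abs(nrml[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    t1 <- c(nrml[2L] * a[3L] - nrml[3L] * a[2L],
            nrml[3L] * a[1L] - nrml[1L] * a[3L],
            nrml[1L] * a[2L] - nrml[2L] * a[1L])
    t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(nrml[2L] * t1[3L] - nrml[3L] * t1[2L],
            nrml[3L] * t1[1L] - nrml[1L] * t1[3L],
            nrml[1L] * t1[2L] - nrml[2L] * t1[1L])
    out[i, ] <- cos(ang[i]) * t1 + sin(ang[i]) * t2
  }
  out
}

# Distance from points to the mesenchymal emitter ring (a circle on the
# hemisphere at polar angle theta_ring).
ring_distance <- function(xyz, geom, theta_ring_deg) {
  R <- geom$radius
  th <- theta_ring_deg * pi / 180
  ring_rho <- R * sin(th)
  ring_z <- -R * cos(th)
  rho <- sqrt(xyz[, 1L]^2 + xyz[, 2L]^2)
  sqrt((rho - ring_rho)^2 + (xyz[, 3L] - ring_z)^2)
}
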