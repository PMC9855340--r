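# All geometry here is in centimetres; unit conversion from DICOM millimetres
# happens at the I/O boundary (plan_io), never in this module.

#' TG-43 reference point: r0 = 1 cm, theta0 = 90 degrees
#' @format Named numeric vector with elements `r0` (cm) and `theta0` (deg).
#' @export
tg43_reference <- c(r0 = 1, theta0 = 90)

vec3 <- function(x, name) {
  if (is.list(x)) x <- unlist(x, use.names = FALSE)
  if (!is.numeric(x) || length(x) != 3L || !all(is.finite(x)))
    bc_domain_error(sprintf("'%s' must be a finite numeric 3-vector", name))
  as.double(x)
}

#' Dwell geometry: center and orientation of one source position
#'
#' @param center 3-vector position of the active-source center, cm.
#' @param orientation 3-vector along the source axis; normalized to unit
#'   length by the constructor (zero norm is an error).
#' @return Object of class `"dwell_geometry"`.
#' @export
dwell_geometry <- function(center, orientation) {
  center <- vec3(center, "center")
  orientation <- vec3(orientation, "orientation")
  nrm <- sqrt(sum(orientation^2))
  if (nrm < 1e-12)
    bc_stop("brachycheck_geometry_error", "orientation vector has zero norm")
  structure(list(center = center, orientation = orientation / nrm),
            class = "dwell_geometry")
}

#' Extract dwell geometry from a 4x4 transform matrix
#'
#' The planning system stores each source position as a homogeneous transform:
#' the third column is the source orientation and the fourth column the center
#' position. The orientation is normalized; the translation is converted to cm
#' when the matrix is given in mm.
#'
#' @param m a 4x4 numeric matrix.
#' @param units units of the translation column, `"cm"` (default) or `"mm"`.
#' @return A [dwell_geometry()].
#' @export
dwell_from_transform <- function(m, units = c("cm", "mm")) {
  units <- match.arg(units)
  if (!is.matrix(m) || !all(dim(m) == c(4L, 4L)) || !all(is.finite(m)))
    bc_stop("brachycheck_geometry_error", "transform must be a finite 4x4 matrix")
  center <- m[1:3, 4]
  if (units == "mm") center <- center / 10
  dwell_geometry(center, m[1:3, 3])
}

#' Tip positions of the hypothetical line source
#'
#' @param geom a [dwell_geometry()].
#' @param L active length, cm (> 0).
#' @return List with 3-vectors `tip1` (center + L/2 * orientation) and `tip2`
#'   (center - L/2 * orientation).
#' @export
source_tips <- function(geom, L) {
  stopifnot_scalar_number(L, "L")
  if (L <= 0) bc_domain_error("active length L must be > 0")
  half <- (L / 2) * geom$orientation
  list(tip1 = geom$center + half, tip2 = geom$center - half)
}

#' Polar coordinates of a point relative to a line source
#'
#' Computes the distance r from the source center, the polar angle theta
#' between the source axis and the line to the point, and the angle beta
#' subtended at the point by the two source tips. beta is evaluated in the
#' plane spanned by the source axis and the point using the two-argument
#' arctangent (quadrant-safe, no acos round-off near 0/180 degrees): with the
#' point at axial offset z and perpendicular offset rho in the source frame,
#' \deqn{\beta = \mathrm{atan2}(\rho, z - L/2) - \mathrm{atan2}(\rho, z + L/2).}
#'
#' @param geom a [dwell_geometry()].
#' @param point 3-vector, cm.
#' @param L active length, cm.
#' @return Object of class `"polar_coords"`: list with `r` (cm), `theta`
#'   (degrees, in \[0, 180\]) and `beta` (radians, >= 0).
#' @export
polar_coords <- function(geom, point, L) {
  point <- vec3(point, "point")
  stopifnot_scalar_number(L, "L")
  if (L <= 0) bc_domain_error("active length L must be > 0")
  d <- point - geom$center
  r2 <- sum(d^2)
  if (r2 == 0)
    bc_near_source_error("verification point coincides with the source center",
                         distance = 0)
  z <- sum(d * geom$orientation)
  rho <- sqrt(max(r2 - z^2, 0))
  r <- sqrt(r2)
  theta <- atan2(rho, z) * 180 / pi
  beta <- abs(atan2(rho, z - L / 2) - atan2(rho, z + L / 2))
  structure(list(r = r, theta = theta, beta = beta), class = "polar_coords")
}

# sin(theta) below this is treated as collinear with the source axis
COLLINEAR_SIN_TOL <- 1e-6

#' Line-source geometry function G_L(r, theta)
#'
#' \deqn{G_L(r,\theta) = \beta / (L r \sin\theta)} off axis, and the closed
#' form \eqn{(r^2 - L^2/4)^{-1}} on the source axis (theta = 0 or, by the
#' symmetry of the segment, theta = 180 degrees). Collinearity is detected by
#' \eqn{\sin\theta < 10^{-6}}. A collinear point with \eqn{r \le L/2} lies
#' inside the source segment and raises a near-source error.
#'
#' @param coords a [polar_coords()].
#' @param L active length, cm.
#' @return Geometry function value in cm^-2.
#' @export
geometry_function <- function(coords, L) {
  if (!inherits(coords, "polar_coords"))
    bc_domain_error("'coords' must be polar_coords")
  stopifnot_scalar_number(L, "L")
  if (L <= 0) bc_domain_error("active length L must be > 0")
  s <- sin(coords$theta * pi / 180)
  if (s < COLLINEAR_SIN_TOL) {
    if (coords$r <= L / 2)
      bc_near_source_error(sprintf(
        "collinear point at r = %.4g cm lies inside the source segment (L/2 = %.4g cm)",
        coords$r, L / 2), distance = coords$r)
    return(1 / (coords$r^2 - L^2 / 4))
  }
  coords$beta / (L * coords$r * s)
}

#' Geometry function at the TG-43 reference point
#'
#' The normalization denominator of the dose-rate equation,
#' \eqn{G_L(r_0 = 1\,\mathrm{cm}, \theta_0 = 90^\circ)}, evaluated through
#' [geometry_function()] itself for the same active length.
#'
#' @param L active length, cm.
#' @return Reference geometry function value in cm^-2.
#' @export
reference_geometry_function <- function(L) {
  geom <- dwell_geometry(c(0, 0, 0), c(0, 0, 1))
  pt <- c(tg43_reference[["r0"]], 0, 0)  # perpendicular axis, theta = 90 deg
  geometry_function(polar_coords(geom, pt, L), L)
}

# Shortest distance from a point to the source segment (capsule distance).
# Used by the near-source guard: the fitted dose model is meaningless for
# points on or inside the source capsule.
segment_distance <- function(geom, point, L) {
  d <- vec3(point, "point") - geom$center
  z <- sum(d * geom$orientation)
  rho2 <- max(sum(d^2) - z^2, 0)
  if (abs(z) <= L / 2) sqrt(rho2) else sqrt(rho2 + (abs(z) - L / 2)^2)
}
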