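# Geographic coordinates on the sphere of lattices.  The quotient square
# QS = QT+ u QT- (two copies of the quotient triangle glued along the
# mirror-symmetric boundary) is a punctured sphere; the spherical map sends
# the incentre of QT to the poles and the boundary to the equator, giving
# every lattice (up to rigid motion and scaling) a latitude and longitude.

#' Incentre coordinate of the quotient triangle
#'
#' The incentre of the right isosceles triangle (0,0), (1,0), (0,1) is
#' (t, t) with `t = 1 - 1/sqrt(2)` (inradius `(2 - sqrt(2))/2`); the rays
#' from the incentre to the vertices bisect the angles 90, 45, 45 degrees.
#' The incentre is the image of the most "generic" oblique lattice and is
#' sent to the poles of the sphere.
#'
#' @return The scalar `t = 1 - 1/sqrt(2)`.
#' @export
qt_incentre <- function() 1 - 1 / sqrt(2)

# Greenwich bearing: planar angle (degrees, atan2 convention) of the
# Greenwich point G = (0, sqrt(2) - 1) as seen from the incentre.  G is the
# intersection of the line through the incentre and the excluded vertex
# (1, 0) with the vertical edge x = 0.
.greenwich_bearing <- function() 157.5

#' Greenwich point of the quotient triangle
#'
#' @return QT coordinates `c(x, y)` of the Greenwich point
#'   `G = (0, sqrt(2) - 1)`.
#' @export
qt_greenwich <- function() c(x = 0, y = sqrt(2) - 1)

# wrap an angle in degrees into (-180, 180]
.wrap180 <- function(m) {
  r <- m %% 360
  ifelse(r > 180, r - 360, ifelse(r == -180, 180, r))
}

.pi_xy <- function(pi_) {
  if (inherits(pi_, "projected_invariant")) c(pi_$x, pi_$y)
  else { stopifnot(is.numeric(pi_), length(pi_) == 2L); as.numeric(pi_) }
}

#' Planar bearing of a QT point from the incentre
#'
#' Two-argument arctangent of `(y - t, x - t)` in degrees, range
#' (-180, 180].  Points with `x = t` return `sign(y - t) * 90` exactly.
#' The incentre itself has no bearing.
#'
#' @param pi_ a `"projected_invariant"` or numeric `c(x, y)`.
#' @param tol radius around the incentre treated as the incentre itself.
#' @return Angle in degrees.
#' @export
qt_bearing <- function(pi_, tol = 1e-12) {
  xy <- .pi_xy(pi_)
  t <- qt_incentre()
  dx <- xy[1] - t; dy <- xy[2] - t
  if (sqrt(dx^2 + dy^2) <= tol)
    stop("bearing undefined at the incentre", call. = FALSE)
  atan2(dy, dx) * 180 / pi
}

#' Longitude of a lattice
#'
#' Anticlockwise angle, in degrees in (-180, 180], from the Greenwich
#' meridian: `mu = wrap(bearing - 157.5)`.  The Greenwich point
#' `G = (0, sqrt(2) - 1)` has longitude 0.  Points on the open segment from
#' the excluded vertex (1, 0) towards the incentre (planar bearing -22.5
#' degrees) receive `+180` rather than `-180`.
#'
#' @inheritParams qt_bearing
#' @return Longitude in degrees.
#' @examples
#' qt_longitude(c(0, 0))  # square lattice: 67.5
#' qt_longitude(c(0, 1))  # hexagonal lattice: -45
#' @export
qt_longitude <- function(pi_, tol = 1e-12) {
  .wrap180(qt_bearing(pi_, tol = tol) - .greenwich_bearing())
}

#' Boundary hit of the incentre ray through a QT point
#'
#' The unique intersection of the ray from the incentre (t, t) through
#' `(x, y)` with the boundary of QT (edges `x = 0`, `y = 0`, `x + y = 1`),
#' found as the minimal positive ray parameter over the three edge lines.
#'
#' @inheritParams qt_bearing
#' @return Numeric `c(x, y)` on the boundary of QT.
#' @export
qt_boundary_hit <- function(pi_, tol = 1e-12) {
  xy <- .pi_xy(pi_)
  t <- qt_incentre()
  d <- xy - c(t, t)
  if (sqrt(sum(d^2)) <= tol)
    stop("boundary hit undefined at the incentre", call. = FALSE)
  lam <- c(if (d[1] < 0) -t / d[1],                    # edge x = 0
           if (d[2] < 0) -t / d[2],                    # edge y = 0
           if (sum(d) > 0) (1 - 2 * t) / sum(d))       # edge x + y = 1
  lam <- lam[lam > 0]
  c(t, t) + min(lam) * d
}

#' Latitude of a lattice
#'
#' The segment from the incentre to the boundary of QT maps linearly onto
#' the meridian arc from the pole to the equator: with
#' `s = |pi - (t,t)| / |boundary_hit(pi) - (t,t)|` in [0, 1], the latitude
#' is `phi = sign * 90 * (1 - s)` degrees.  Mirror-symmetric lattices
#' (sign 0, boundary points) lie on the equator, `phi = 0`; the incentre
#' with sign +1/-1 is the north/south pole, `phi = +90/-90`.
#'
#' @param pi_ a `"projected_invariant"`.
#' @param tol tolerance for the boundary/incentre coincidence tests.
#' @return Latitude in degrees in [-90, 90].
#' @export
qt_latitude <- function(pi_, tol = 1e-9) {
  stopifnot(inherits(pi_, "projected_invariant"))
  x <- pi_$x; y <- pi_$y
  on_boundary <- (x <= tol || y <= tol || x + y >= 1 - tol)
  if (pi_$sign == 0L) {
    if (!on_boundary)
      stop("inconsistent invariant: interior QT point with sign 0",
           call. = FALSE)
    return(0)
  }
  t <- qt_incentre()
  d <- sqrt((x - t)^2 + (y - t)^2)
  if (d <= tol) return(90 * pi_$sign)
  hit <- qt_boundary_hit(pi_)
  s <- d / sqrt(sum((hit - c(t, t))^2))
  pi_$sign * 90 * (1 - min(1, s))
}

#' Spherical map: latitude and longitude of a lattice
#'
#' Combines [qt_latitude()] and [qt_longitude()].  Positively oriented
#' lattices land on the northern hemisphere, negatively oriented ones on the
#' southern, mirror-symmetric ones on the equator.  At the poles (incentre
#' points) the longitude is undefined and flagged.
#'
#' @inheritParams qt_latitude
#' @return An object of class `"sphere_coord"`: list with `latitude`,
#'   `longitude` (degrees; `NA` at the poles) and `defined_longitude`.
#' @examples
#' sb <- selling_reduce(basis2d(c(1, 0), c(0, 1)))
#' spherical_map(projected_invariant(root_invariant(sb), 0))  # (0, 67.5)
#' @export
spherical_map <- function(pi_, tol = 1e-9) {
  phi <- qt_latitude(pi_, tol = tol)
  t <- qt_incentre()
  at_pole <- sqrt((pi_$x - t)^2 + (pi_$y - t)^2) <= tol
  structure(list(latitude = phi,
                 longitude = if (at_pole) NA_real_ else qt_longitude(pi_),
                 defined_longitude = !at_pole),
            class = "sphere_coord")
}

#' @export
print.sphere_coord <- function(x, ...) {
  cat(sprintf("<sphere_coord>  latitude %g deg, longitude %s\n",
              signif(x$latitude, 8),
              if (x$defined_longitude) paste0(signif(x$longitude, 8), " deg")
              else "undefined (pole)"))
  invisible(x)
}

#' Side ratio of the Greenwich centred-rectangular lattices
#'
#' The Greenwich point `G = (0, sqrt(2) - 1)` lies on the vertical edge of
#' QT, which carries centred rectangular lattices with conventional cell
#' `2a x 2b`, `b/a < sqrt(3)` (superbase `(2a, 0), (-a, b), (-a, -b)`, root
#' invariant `(sqrt(b^2 - a^2), a sqrt(2), a sqrt(2))`).  This solves
#' `y(b/a) = sqrt(2) - 1` on that branch for the side ratio `b/a`.
#'
#' @return The ratio `b/a` (about 1.098, i.e. 1.1 to two significant
#'   figures).
#' @export
greenwich_ratio <- function() {
  yG <- qt_greenwich()[["y"]]
  f <- function(q) {
    u <- sqrt(q^2 - 1)                       # r12 for a = 1
    3 * u / (u + 2 * sqrt(2)) - yG
  }
  stats::uniroot(f, c(1 + 1e-12, sqrt(3)), tol = 1e-14)$root
}
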