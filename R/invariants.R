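# Root invariants, chirality sign, projected invariants and derived
# quantities.  The root invariant RI = (r12, r01, r02) with r_ij = sqrt(p_ij)
# is a complete isometry invariant of a planar lattice; adding the sign makes
# it complete up to rigid motion.

#' Construct a root invariant from its components
#'
#' @param r12,r01,r02 root products (angstroms), `0 <= r12 <= r01 <= r02`
#'   and `r01 > 0`.
#' @return An object of class `"root_invariant"`: named numeric triple.
#' @export
root_invariant_values <- function(r12, r01, r02) {
  r <- c(r12 = r12, r01 = r01, r02 = r02)
  if (anyNA(r) || !all(is.finite(r)))
    stop("root products must be finite", call. = FALSE)
  if (r[1] < 0 || r[1] > r[2] || r[2] > r[3])
    stop("root invariant must satisfy 0 <= r12 <= r01 <= r02", call. = FALSE)
  if (r[2] <= 0)
    stop("degenerate root invariant: r01 must be positive", call. = FALSE)
  structure(r, class = "root_invariant")
}

#' @rdname root_invariant_values
#' @param x numeric 3-vector or `"root_invariant"`.
#' @export
as_root_invariant <- function(x) {
  if (inherits(x, "root_invariant")) return(x)
  stopifnot(is.numeric(x), length(x) == 3L)
  root_invariant_values(x[[1]], x[[2]], x[[3]])
}

#' Root invariant of an obtuse superbase
#'
#' Square roots of the sorted conorms, `r_ij = sqrt(p_ij)`.  Sorting agrees
#' with the canonical length order of the superbase
#' (`|v1| <= |v2| <= |v0|` implies `r12 <= r01 <= r02`).
#'
#' @param sb an `"obtuse_superbase"` from [selling_reduce()].
#' @return A `"root_invariant"` triple (angstroms).
#' @examples
#' root_invariant(selling_reduce(basis2d(c(1, 0), c(0, 1))))  # (0, 1, 1)
#' @export
root_invariant <- function(sb) {
  stopifnot(inherits(sb, "obtuse_superbase"))
  p <- sort(sb$p)           # canonical order already sorts; sort() is a guard
  root_invariant_values(sqrt(p[[1]]), sqrt(p[[2]]), sqrt(p[[3]]))
}

#' @export
print.root_invariant <- function(x, ...) {
  cat(sprintf("<root_invariant>  (r12, r01, r02) = (%g, %g, %g)\n",
              signif(x[[1]], 8), signif(x[[2]], 8), signif(x[[3]], 8)))
  invisible(x)
}

#' Chirality sign of a lattice
#'
#' Mirror-symmetric (achiral) lattices have sign 0; these are exactly the
#' lattices whose root invariant has a repeated component or `r12 = 0`
#' (rectangular, centred rectangular, square, hexagonal).  Otherwise the
#' three superbase vectors have pairwise distinct lengths; ordering them
#' `|v1| < |v2| < |v0|`, the sign is the sign of `det[v1 v2]`: +1 for a
#' positively oriented canonical pair, -1 for its mirror image.
#'
#' @param sb an `"obtuse_superbase"` from [selling_reduce()].
#' @param tol relative tolerance of the mirror-symmetry test, as a fraction
#'   of the size `sigma = r12 + r01 + r02`.  The default 1e-9 suits exact
#'   synthetic input; experimental cells need a larger, explicit choice
#'   (near-symmetric lattices are deliberately not snapped by default).
#' @return -1, 0 or +1.
#' @export
lattice_sign <- function(sb, tol = 1e-9) {
  stopifnot(inherits(sb, "obtuse_superbase"))
  r <- sqrt(sort(sb$p))
  sigma <- sum(r)
  if (sigma <= 0) stop("degenerate superbase", call. = FALSE)
  if (r[1] <= tol * sigma || (r[2] - r[1]) <= tol * sigma ||
      (r[3] - r[2]) <= tol * sigma)
    return(0L)
  as.integer(sign(sb$det))
}

#' Size of a root invariant
#'
#' `sigma = r12 + r01 + r02`, the scale factor removed by projection to the
#' quotient triangle.
#'
#' @param ri a `"root_invariant"` (or numeric triple).
#' @return Positive scalar (angstroms).
#' @export
ri_size <- function(ri) {
  ri <- as_root_invariant(ri)
  sum(ri)
}

#' Projected invariant in the quotient triangle
#'
#' Divides the root invariant by its size `sigma` and maps the normalized
#' triple to coordinates of the isosceles right-angled quotient triangle QT
#' with vertices (0,0), (1,0), (0,1):
#' `x = (r02 - r01)/sigma`, `y = 3 r12/sigma`.
#' The map is scale-invariant, sends square lattices to (0,0), hexagonal
#' lattices to (0,1), rectangular lattices to the edge `y = 0`, centred
#' rectangular lattices to the edge `x = 0` or the hypotenuse `x + y = 1`,
#' and oblique lattices to the interior.  The boundary of QT carries exactly
#' the mirror-symmetric lattices, so `sign = 0` iff (x, y) lies on it.
#'
#' @param ri a `"root_invariant"` (or numeric triple).
#' @param sign chirality sign in {-1, 0, +1} (see [lattice_sign()]).
#' @return An object of class `"projected_invariant"`: list with `x`, `y`,
#'   `sign`.
#' @examples
#' sb <- selling_reduce(basis2d(c(1, 0), c(-0.5, sqrt(3) / 2)))
#' projected_invariant(root_invariant(sb), lattice_sign(sb))  # (0, 1)
#' @export
projected_invariant <- function(ri, sign = 0) {
  ri <- as_root_invariant(ri)
  if (!sign %in% c(-1, 0, 1)) stop("sign must be -1, 0 or +1", call. = FALSE)
  sigma <- sum(ri)
  structure(list(x = (ri[[3]] - ri[[2]]) / sigma,
                 y = 3 * ri[[1]] / sigma,
                 sign = as.integer(sign)),
            class = "projected_invariant")
}

#' @rdname projected_invariant
#' @param x,y QT coordinates, `0 <= x < 1`, `0 <= y <= 1`, `x + y <= 1`.
#' @export
projected_invariant_values <- function(x, y, sign = 0) {
  if (anyNA(c(x, y)) || !all(is.finite(c(x, y))))
    stop("QT coordinates must be finite", call. = FALSE)
  if (x < 0 || y < 0 || x >= 1 || y > 1 || x + y > 1 + 1e-12)
    stop("point outside the quotient triangle QT", call. = FALSE)
  if (!sign %in% c(-1, 0, 1)) stop("sign must be -1, 0 or +1", call. = FALSE)
  structure(list(x = x, y = y, sign = as.integer(sign)),
            class = "projected_invariant")
}

#' @export
print.projected_invariant <- function(x, ...) {
  cat(sprintf("<projected_invariant>  (x, y) = (%g, %g)  sign = %+d\n",
              signif(x$x, 8), signif(x$y, 8), x$sign))
  invisible(x)
}

#' Invert the projection: root invariant on the unit-size slice
#'
#' Returns the root invariant with `sigma = 1` whose projected invariant is
#' `(x, y)`; any positive multiple realizes the same QT point.
#'
#' @param x,y QT coordinates.
#' @return A `"root_invariant"` with components summing to 1.
#' @export
ri_from_qt <- function(x, y) {
  r12 <- y / 3
  r01 <- (1 - r12 - x) / 2
  r02 <- (1 - r12 + x) / 2
  root_invariant_values(r12, r01, r02)
}

#' Quadratic invariant of a reduced cell
#'
#' Homogenized square roots of the reduced metric tensor
#' `(q11, q12, q22) = (a^2, a b cos(gamma), b^2)` of the non-acute reduced
#' basis (`q12 <= 0`): `QI = (sqrt(q11), sqrt(-q12), sqrt(q22))`, all in the
#' original length units.
#'
#' @param rc a `"reduced_cell"` from [reduced_cell()].
#' @return Named numeric triple `(tau11, tau12, tau22)` of class
#'   `"quadratic_invariant"`.
#' @export
quadratic_invariant <- function(rc) {
  stopifnot(inherits(rc, "reduced_cell"))
  q12 <- rc$a * rc$b * cospi(rc$gamma / 180)
  structure(c(tau11 = rc$a, tau12 = sqrt(max(0, -q12)), tau22 = rc$b),
            class = "quadratic_invariant")
}

#' L-infinity distance between root invariants
#'
#' `max(|dr12|, |dr01|, |dr02|)`; a metric on root-invariant triples.  The
#' calibrated metrics of the full lattice-space theory are out of scope; this
#' distance supports nearest-neighbour style comparisons in applications.
#'
#' @param a,b `"root_invariant"` objects (or numeric triples).
#' @return Non-negative scalar (angstroms).
#' @export
ri_distance <- function(a, b) {
  a <- as_root_invariant(a); b <- as_root_invariant(b)
  max(abs(as.numeric(a) - as.numeric(b)))
}

#' Dissymmetry: distance to each higher-symmetry subspace
#'
#' Euclidean distances in QT coordinates from a projected invariant to the
#' subspaces of the four non-generic Bravais classes: the square vertex
#' (0,0) (`tp`), the hexagonal vertex (0,1) (`hp`), the rectangular edge
#' `y = 0` (`op`), and the centred-rectangular union
#' `{x = 0} U {x + y = 1}` (`oc`).  Each distance vanishes exactly on its
#' subspace, giving a continuous pseudosymmetry measure.
#'
#' @param pi_ a `"projected_invariant"`.
#' @return Named numeric vector with components `tp`, `hp`, `op`, `oc`.
#' @export
dissymmetry <- function(pi_) {
  stopifnot(inherits(pi_, "projected_invariant"))
  x <- pi_$x; y <- pi_$y
  c(tp = sqrt(x^2 + y^2),
    hp = sqrt(x^2 + (y - 1)^2),
    op = .dist_segment(x, y, c(0, 0), c(1, 0)),
    oc = min(.dist_segment(x, y, c(0, 0), c(0, 1)),
             .dist_segment(x, y, c(1, 0), c(0, 1))))
}

# Euclidean distance from point (x, y) to the segment [p, q]
.dist_segment <- function(x, y, p, q) {
  d <- q - p
  t <- ((x - p[1]) * d[1] + (y - p[2]) * d[2]) / sum(d^2)
  t <- max(0, min(1, t))
  sqrt((x - p[1] - t * d[1])^2 + (y - p[2] - t * d[2])^2)
}

#' Full invariant summary of a single lattice
#'
#' Convenience wrapper running the whole chain: Selling reduction, root
#' invariant, chirality sign, reduced cell, projected invariant, Bravais
#' label and spherical coordinates.
#'
#' @param basis a [basis2d()] or [cell2d()] object.
#' @param sym_tol mirror-symmetry tolerance (see [lattice_sign()]), also
#'   used as the Bravais classification tolerance.
#' @return A list with components `superbase`, `ri`, `sign`, `sigma`,
#'   `cell` (reduced cell), `pi` (projected invariant), `bravais`, `sphere`.
#' @examples
#' lattice_invariants(basis2d(c(1.9, 0), c(-0.18, 3.63)))
#' @export
lattice_invariants <- function(basis, sym_tol = 1e-9) {
  sb <- selling_reduce(basis)
  ri <- root_invariant(sb)
  sgn <- lattice_sign(sb, tol = sym_tol)
  pi_ <- projected_invariant(ri, sgn)
  list(superbase = sb,
       ri = ri,
       sign = sgn,
       sigma = ri_size(ri),
       cell = reduced_cell(sb, sym_tol = sym_tol),
       pi = pi_,
       bravais = bravais_class(pi_, tol = sym_tol),
       # sign = 0 displaces (x, y) from the exact boundary by at most
       # 3 * sym_tol, so the consistency test must be at least that wide
       sphere = spherical_map(pi_, tol = 3 * sym_tol))
}
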