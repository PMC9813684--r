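#' geolattice: continuous invariants and geographic maps of 2D lattices
#'
#' A two-dimensional lattice is the set of all integer combinations of two
#' independent plane vectors.  Conventional discrete classifications (five
#' Bravais classes, wallpaper groups) are discontinuous under perturbation of
#' the basis, which makes them ill-suited to noisy experimental cells.  This
#' package classifies planar lattices *continuously*: every lattice is reduced
#' to its obtuse superbase, summarised by the complete root invariant
#' RI = (r12, r01, r02) with a chirality sign, projected to scale-free
#' coordinates in the quotient triangle QT, and finally placed on a sphere by
#' geographic latitude/longitude coordinates.  A mapping pipeline applies the
#' same machinery to tables of three-dimensional unit cells by extracting the
#' three sublattices spanned by pairs of cell vectors.
#'
#' @section Main entry points:
#' \itemize{
#'   \item [selling_reduce()], [root_invariant()], [projected_invariant()] --
#'     the reduction/invariant chain for a single lattice;
#'   \item [spherical_map()] -- latitude and longitude on the sphere;
#'   \item [bravais_class()] -- tolerance-aware Bravais labels;
#'   \item [map_table()], [bin_qt()], [bin_sphere()] -- the batch pipeline;
#'   \item [gen_lattices()], [gen_cell_table()] -- synthetic test populations.
#' }
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# constructors / validators

.is_num2 <- function(v) is.numeric(v) && length(v) == 2L && all(is.finite(v))

#' Planar lattice basis
#'
#' Two independent vectors spanning a lattice in the plane.  The absolute
#' determinant of the 2x2 matrix with columns `v1`, `v2` equals the area of
#' the primitive unit cell.
#'
#' @param v1,v2 numeric 2-vectors (angstroms).
#' @return An object of class `"basis2d"`: a list with elements `v1`, `v2`
#'   and `det`.
#' @examples
#' basis2d(c(1, 0), c(0, 1))
#' @export
basis2d <- function(v1, v2) {
  if (!.is_num2(v1) || !.is_num2(v2))
    stop("basis vectors must be finite numeric 2-vectors", call. = FALSE)
  d <- v1[1] * v2[2] - v1[2] * v2[1]
  scale <- max(sum(v1^2), sum(v2^2))
  if (scale == 0 || abs(d) <= 1e-12 * scale)
    stop("degenerate basis: vectors are collinear or zero", call. = FALSE)
  structure(list(v1 = as.numeric(v1), v2 = as.numeric(v2), det = d),
            class = "basis2d")
}

#' @export
print.basis2d <- function(x, ...) {
  cat("<basis2d>  v1 = (", paste(signif(x$v1, 6), collapse = ", "),
      ")  v2 = (", paste(signif(x$v2, 6), collapse = ", "),
      ")  cell area ", signif(abs(x$det), 6), "\n", sep = "")
  invisible(x)
}

#' 2D cell parameters
#'
#' Parameter form of a planar lattice basis: side lengths `a`, `b` and the
#' inter-vector angle `gamma` in degrees.
#'
#' @param a,b side lengths (angstroms), positive.
#' @param gamma angle between the basis vectors, degrees, in (0, 180).
#' @return An object of class `"cell2d"`.
#' @export
cell2d <- function(a, b, gamma) {
  if (!is.numeric(a) || !is.numeric(b) || !is.numeric(gamma) ||
      anyNA(c(a, b, gamma)) || !all(is.finite(c(a, b, gamma))))
    stop("cell parameters must be finite numbers", call. = FALSE)
  if (a <= 0 || b <= 0 || gamma <= 0 || gamma >= 180)
    stop("invalid 2D cell: need a > 0, b > 0, 0 < gamma < 180", call. = FALSE)
  structure(list(a = a, b = b, gamma = gamma), class = "cell2d")
}

#' 3D cell parameters
#'
#' Conventional unit-cell description of a three-dimensional lattice.  The
#' three angles must admit a realizable cell (positive Gram determinant).
#'
#' @param a,b,c edge lengths (angstroms), positive.
#' @param alpha,beta,gamma inter-edge angles in degrees, each in (0, 180);
#'   `alpha` is the angle between edges b and c, `beta` between a and c,
#'   `gamma` between a and b.
#' @param id optional free-text label.
#' @return An object of class `"cell3d"`.
#' @export
cell3d <- function(a, b, c, alpha, beta, gamma, id = "") {
  p <- c(a, b, c, alpha, beta, gamma)
  if (!is.numeric(p) || anyNA(p) || !all(is.finite(p)))
    stop("cell parameters must be finite numbers", call. = FALSE)
  if (any(c(a, b, c) <= 0) || any(c(alpha, beta, gamma) <= 0) ||
      any(c(alpha, beta, gamma) >= 180))
    stop("invalid 3D cell: lengths > 0, angles in (0, 180)", call. = FALSE)
  ca <- cospi(alpha / 180); cb <- cospi(beta / 180); cg <- cospi(gamma / 180)
  # Gram determinant of the unit direction vectors must be positive
  g <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (g <= 1e-12)
    stop("non-realizable angle triple (Gram determinant <= 0)", call. = FALSE)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, id = as.character(id)),
            class = "cell3d")
}

#' Embed 2D cell parameters as a basis
#'
#' Right-handed embedding with the first vector along +x:
#' `v1 = (a, 0)`, `v2 = (b cos(gamma), b sin(gamma))` with `sin(gamma) > 0`.
#'
#' @param cell a [cell2d()] object.
#' @return A [basis2d()] object.
#' @examples
#' cell_to_basis(cell2d(1, 1, 120))
#' @export
cell_to_basis <- function(cell) {
  stopifnot(inherits(cell, "cell2d"))
  g <- cell$gamma / 180
  basis2d(c(cell$a, 0), c(cell$b * cospi(g), cell$b * sinpi(g)))
}

#' Orthogonalize 3D cell parameters into basis vectors
#'
#' Standard crystallographic convention: `v1` along x, `v2` in the xy-plane
#' with positive y-component, `v3` with positive z-component.
#'
#' @param cell a [cell3d()] object.
#' @return A 3x3 matrix whose rows are the basis vectors v1, v2, v3.
#' @export
basis3d_from_cell <- function(cell) {
  stopifnot(inherits(cell, "cell3d"))
  ca <- cospi(cell$alpha / 180)
  cb <- cospi(cell$beta / 180)
  cg <- cospi(cell$gamma / 180); sg <- sinpi(cell$gamma / 180)
  v1 <- c(cell$a, 0, 0)
  v2 <- c(cell$b * cg, cell$b * sg, 0)
  cx <- cb
  cy <- (ca - cb * cg) / sg
  cz2 <- 1 - cx^2 - cy^2
  if (cz2 <= 0)
    stop("non-realizable angle triple for 3D cell", call. = FALSE)
  v3 <- cell$c * c(cx, cy, sqrt(cz2))
  rbind(v1 = v1, v2 = v2, v3 = v3)
}

# ---------------------------------------------------------------------------
# Selling (obtuse-superbase) reduction

#' Obtuse-superbase reduction of a planar lattice
#'
#' Extends the basis to the superbase `v0 = -v1 - v2`, `v1`, `v2` and applies
#' Selling steps until every conorm `p_ij = -v_i . v_j` is non-negative, i.e.
#' all pairwise angles between the three vectors are non-acute.  Each step
#' picks the first acute pair in the scan order (1,2), (0,1), (0,2) and
#' replaces `v_i -> -v_i`, `v_k -> v_k + 2 v_i` (third index `k`), which
#' keeps the zero sum and strictly decreases `|v0|^2 + |v1|^2 + |v2|^2`
#' by `4 v_i . v_j`, so the loop terminates.  The result is stored in
#' canonical length order `|v1| <= |v2| <= |v0|`, which sorts the conorm
#' triple `(p12, p01, p02)` ascending.
#'
#' Every lattice has an obtuse superbase, and for planar lattices it is
#' unique up to isometry, which makes the conorms a complete foundation for
#' the invariants in [root_invariant()].
#'
#' @param basis a [basis2d()] object (or a [cell2d()], embedded first).
#' @param tol acuteness tolerance, relative to `max |v_i|^2`; a pair is
#'   treated as acute only when `v_i . v_j` exceeds `tol * max|v|^2`.
#' @param max_iter iteration cap guarding against floating-point pathologies.
#' @return An object of class `"obtuse_superbase"`: list with 2-vectors
#'   `v0`, `v1`, `v2`, the conorm triple `p = c(p12, p01, p02)` (clamped at
#'   zero), and `det` = det of the columns (v1, v2) of the canonical pair.
#' @examples
#' selling_reduce(basis2d(c(1, 0), c(0.9, 1)))
#' @export
selling_reduce <- function(basis, tol = 1e-12, max_iter = 10000L) {
  if (inherits(basis, "cell2d")) basis <- cell_to_basis(basis)
  stopifnot(inherits(basis, "basis2d"))
  V <- rbind(basis$v1, basis$v2, -basis$v1 - basis$v2)  # rows v1, v2, v0
  # scan order (1,2), (0,1), (0,2) as row pairs (1,2), (3,1), (3,2);
  # for pair (i, j) the replaced vector is v_i (superbase index order)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter)
      stop("Selling reduction failed to terminate (iteration cap)",
           call. = FALSE)
    eps <- tol * max(rowSums(V^2))
    d12 <- sum(V[1, ] * V[2, ])
    if (d12 > eps) {                       # pair (v1, v2): replace v1
      V <- rbind(-V[1, ], V[2, ], V[3, ] + 2 * V[1, ])
      next
    }
    d01 <- sum(V[3, ] * V[1, ])
    if (d01 > eps) {                       # pair (v0, v1): replace v0
      V <- rbind(V[1, ], V[2, ] + 2 * V[3, ], -V[3, ])
      next
    }
    d02 <- sum(V[3, ] * V[2, ])
    if (d02 > eps) {                       # pair (v0, v2): replace v0
      V <- rbind(V[1, ] + 2 * V[3, ], V[2, ], -V[3, ])
      next
    }
    break
  }
  .canonical_superbase(V[1, ], V[2, ], V[3, ])
}

# order vectors by length |v1| <= |v2| <= |v0|; this sorts the conorms
# (p12, p01, p02) ascending because |v1|^2 = p12 + p01, |v2|^2 = p12 + p02,
# |v0|^2 = p01 + p02.  Residual ties are genuine symmetries.
.canonical_superbase <- function(v1, v2, v0) {
  W <- rbind(v1, v2, v0)
  W <- W[order(rowSums(W^2)), , drop = FALSE]
  v1 <- W[1, ]; v2 <- W[2, ]; v0 <- W[3, ]
  p <- c(p12 = -sum(v1 * v2), p01 = -sum(v0 * v1), p02 = -sum(v0 * v2))
  p <- pmax(p, 0) + 0      # "+ 0" normalizes a signed zero
  structure(list(v0 = v0, v1 = v1, v2 = v2, p = p,
                 det = v1[1] * v2[2] - v1[2] * v2[1]),
            class = "obtuse_superbase")
}

#' @export
print.obtuse_superbase <- function(x, ...) {
  cat("<obtuse_superbase>\n")
  cat("  v1 = (", paste(signif(x$v1, 6), collapse = ", "), ")\n", sep = "")
  cat("  v2 = (", paste(signif(x$v2, 6), collapse = ", "), ")\n", sep = "")
  cat("  v0 = (", paste(signif(x$v0, 6), collapse = ", "), ")\n", sep = "")
  cat("  conorms (p12, p01, p02) = (",
      paste(signif(x$p, 6), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Reduced cell of a lattice
#'
#' The non-acute reduced cell read off the canonical obtuse superbase:
#' `a = |v1| <= b = |v2|` and `gamma = angle(v1, v2)` in `[90, 180)` degrees
#' (non-acute because `p12 >= 0`).  Together with the chirality sign this
#' parameter triple represents the lattice up to rigid motion.
#'
#' @param sb an `"obtuse_superbase"` from [selling_reduce()].
#' @param sym_tol relative tolerance for the mirror-symmetry test passed to
#'   [lattice_sign()].
#' @return An object of class `"reduced_cell"`: list with `a`, `b`, `gamma`
#'   (degrees) and `sign` in {-1, 0, +1}.
#' @export
reduced_cell <- function(sb, sym_tol = 1e-9) {
  stopifnot(inherits(sb, "obtuse_superbase"))
  a <- sqrt(sum(sb$v1^2)); b <- sqrt(sum(sb$v2^2))
  cg <- max(-1, min(1, -sb$p[["p12"]] / (a * b)))
  structure(list(a = a, b = b, gamma = acos(cg) * 180 / pi,
                 sign = lattice_sign(sb, tol = sym_tol)),
            class = "reduced_cell")
}

#' @export
print.reduced_cell <- function(x, ...) {
  cat(sprintf("<reduced_cell>  a = %g  b = %g  gamma = %g deg  sign = %+d\n",
              signif(x$a, 6), signif(x$b, 6), signif(x$gamma, 6), x$sign))
  invisible(x)
}

#' Inverse design: build a lattice basis from its root invariant
#'
#' Reconstructs a basis realizing a given root invariant and chirality sign,
#' so that [selling_reduce()] followed by [root_invariant()] and
#' [lattice_sign()] recovers the inputs (round-trip identity).  Conorms are
#' recovered as `p_ij = r_ij^2`; the basis is embedded with
#' `v1 = (|v1|, 0)` and `v2 = (-p12/|v1|, h)`, `h > 0`, with the y-component
#' negated when `sign = -1`.
#'
#' @param ri a [root_invariant()] triple (or numeric 3-vector, sorted
#'   ascending, with `r01 > 0`).
#' @param sign chirality sign in {-1, 0, +1}.
#' @return A [basis2d()] object.
#' @examples
#' lattice_from_ri(root_invariant_values(0, 1, 1))  # unit square lattice
#' @export
lattice_from_ri <- function(ri, sign = 0) {
  ri <- as_root_invariant(ri)
  if (!sign %in% c(-1, 0, 1)) stop("sign must be -1, 0 or +1", call. = FALSE)
  p12 <- ri[[1]]^2; p01 <- ri[[2]]^2; p02 <- ri[[3]]^2
  if (p01 <= 0)
    stop("degenerate root invariant: r01 must be positive", call. = FALSE)
  l1 <- sqrt(p12 + p01)
  l2 <- sqrt(p12 + p02)
  x2 <- -p12 / l1
  h2 <- l2^2 - x2^2
  if (h2 <= 0) stop("invalid root invariant: no planar realization",
                    call. = FALSE)
  h <- sqrt(h2)
  if (sign < 0) h <- -h
  basis2d(c(l1, 0), c(x2, h))
}
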