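# Synthetic lattice and cell-table generators.  Every generated basis
# carries its ground-truth root invariant, Bravais label and chirality sign
# (closed forms per family), so the whole reduction/invariant chain can be
# validated without any external database.

.gl_families <- c("square", "hexagonal", "rectangular",
                  "centred_rectangular", "oblique", "mixed")

#' Random unimodular 2x2 integer matrix
#'
#' Product of `k` random elementary matrices (shears with unit diagonal,
#' swaps, and sign flips), so the determinant is exactly +1 or -1.  Entries
#' are capped at `max_entry` by rejecting overgrown products, which bounds
#' coordinate growth when re-basing test lattices.
#'
#' @param k number of elementary factors; `k = 0` returns the identity.
#' @param max_entry largest allowed absolute entry.
#' @return 2x2 integer matrix with determinant +1 or -1.
#' @export
random_unimodular <- function(k, max_entry = 5L) {
  stopifnot(k >= 0)
  M <- diag(2)
  for (i in seq_len(k)) {
    repeat {
      kind <- sample(3L, 1L)
      E <- switch(kind,
        { m <- sample(c(-2L, -1L, 1L, 2L), 1L)
          matrix(c(1, 0, m, 1), 2) },                 # column shear
        { m <- sample(c(-2L, -1L, 1L, 2L), 1L)
          matrix(c(1, m, 0, 1), 2) },                 # row shear
        matrix(c(0, 1, 1, 0), 2))                     # swap (det -1)
      Mn <- M %*% E
      if (max(abs(Mn)) <= max_entry) { M <- Mn; break }
    }
  }
  storage.mode(M) <- "integer"
  M
}

# ground-truth record constructor
.gl_record <- function(basis, label, ri, sign) {
  list(basis = basis, label = label,
       ri = sort(as.numeric(ri)), sign = as.integer(sign))
}

# rotate a basis by a random angle and re-base by a random unimodular
# matrix; neither changes the lattice's invariants
.gl_scramble <- function(basis, rotate = TRUE, rebase = TRUE) {
  v1 <- basis$v1; v2 <- basis$v2
  if (rebase) {
    M <- random_unimodular(sample(0:4, 1L))
    w1 <- M[1, 1] * v1 + M[1, 2] * v2
    w2 <- M[2, 1] * v1 + M[2, 2] * v2
    v1 <- w1; v2 <- w2
  }
  if (rotate) {
    th <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    v1 <- as.numeric(R %*% v1); v2 <- as.numeric(R %*% v2)
  }
  basis2d(v1, v2)
}

#' Generate synthetic lattices with ground truth
#'
#' Draws `n` lattices from one of the five planar Bravais families (or a
#' mixture), each returned with its true root invariant (closed form per
#' family), Bravais label and chirality sign.  Bases are optionally
#' scrambled by a random rotation and random unimodular re-basing, which
#' leaves all invariants unchanged.  The oblique family samples reduced
#' cells `a <= b`, obtuse `gamma`, avoiding a guard band of 1e-6 around
#' the symmetric loci so ground-truth signs are unambiguous; with
#' `mirror_pairs = TRUE` it emits each lattice together with its reflection
#' (equal RI, opposite sign), in order, giving exact chirality balance.
#'
#' @param family one of `"square"`, `"hexagonal"`, `"rectangular"`,
#'   `"centred_rectangular"`, `"oblique"`, `"mixed"`.
#' @param n number of lattices (with `mirror_pairs`, `n` must be even and
#'   counts pairs of records).
#' @param seed integer seed; the same spec always yields the same output.
#' @param a_range range of the base length draw (angstroms).
#' @param scramble apply random rotation + unimodular re-basing.
#' @param mirror_pairs oblique only: emit mirror pairs.
#' @return List of records, each a list with `basis` ([basis2d()]),
#'   `label`, `ri` (true root invariant, sorted), `sign`.
#' @export
gen_lattices <- function(family = "mixed", n = 100L, seed = NULL,
                         a_range = c(0.5, 5), scramble = TRUE,
                         mirror_pairs = FALSE) {
  family <- match.arg(family, .gl_families)
  stopifnot(n >= 0, length(a_range) == 2L, a_range[1] > 0,
            a_range[2] > a_range[1])
  if (!is.null(seed)) set.seed(seed)
  if (mirror_pairs && family != "oblique")
    stop("mirror_pairs applies to the oblique family", call. = FALSE)
  if (mirror_pairs && n %% 2L != 0L)
    stop("mirror_pairs needs an even n", call. = FALSE)

  one <- function(fam) {
    a <- stats::runif(1, a_range[1], a_range[2])
    switch(fam,
      square = .gl_record(basis2d(c(a, 0), c(0, a)), "tp", c(0, a, a), 0),
      hexagonal = .gl_record(basis2d(c(a, 0), c(-a / 2, a * sqrt(3) / 2)),
                             "hp", rep(a / sqrt(2), 3), 0),
      rectangular = {
        b <- a * stats::runif(1, 1 + 1e-3, 3)
        .gl_record(basis2d(c(a, 0), c(0, b)), "op", c(0, a, b), 0)
      },
      centred_rectangular = {
        # conventional cell 2a x 2b; avoid b/a near 1 (square) and
        # sqrt(3) (hexagonal) so the label is unambiguous
        repeat {
          q <- stats::runif(1, 1 + 1e-3, 3)
          if (abs(q - sqrt(3)) > 1e-3) break
        }
        b <- a * q
        .gl_record(basis2d(c(2 * a, 0), c(-a, b)), "oc",
                   c(sqrt(b^2 - a^2), a * sqrt(2), a * sqrt(2)), 0)
      },
      oblique = .gl_oblique(a, a_range))
  }

  recs <- vector("list", n)
  i <- 1L
  while (i <= n) {
    fam <- if (family == "mixed")
      sample(c("square", "hexagonal", "rectangular",
               "centred_rectangular", "oblique"), 1L)
    else family
    r <- one(fam)
    if (mirror_pairs) {
      m <- basis2d(r$basis$v1 * c(1, -1), r$basis$v2 * c(1, -1))
      rm <- .gl_record(m, r$label, r$ri, -r$sign)
      if (scramble) {
        r$basis <- .gl_scramble(r$basis)
        rm$basis <- .gl_scramble(rm$basis)
      }
      recs[[i]] <- r; recs[[i + 1L]] <- rm
      i <- i + 2L
    } else {
      if (scramble) r$basis <- .gl_scramble(r$basis)
      recs[[i]] <- r
      i <- i + 1L
    }
  }
  recs
}

# sample an oblique lattice as a reduced basis: a <= b, gamma in (90, 180)
# restricted so the superbase (v1, v2, -v1-v2) is already obtuse
# (cos gamma >= -a/(2b)); resample while any pair of root products is
# closer than the guard band, so sign ground truth is unambiguous
.gl_oblique <- function(a, a_range, guard = 1e-6) {
  repeat {
    b <- a * stats::runif(1, 1, 2.5)
    cg <- stats::runif(1, -a / (2 * b), 0)
    v1 <- c(a, 0); v2 <- c(b * cg, b * sqrt(1 - cg^2))
    v0 <- -v1 - v2
    p <- c(-sum(v1 * v2), -sum(v0 * v1), -sum(v0 * v2))
    if (any(p < 0)) next
    r <- sort(sqrt(p))
    if (r[1] < guard * sum(r) || diff(r)[1] < guard * sum(r) ||
        diff(r)[2] < guard * sum(r)) next
    # true sign: order the superbase vectors by length, det of shortest two
    W <- rbind(v1, v2, v0)
    W <- W[order(rowSums(W^2)), ]
    s <- sign(W[1, 1] * W[2, 2] - W[1, 2] * W[2, 1])
    return(.gl_record(basis2d(v1, v2), "mp", r, s))
  }
}

#' Generate a synthetic 3D cell table
#'
#' Emulates a heterogeneous crystal-structure cell table: a seeded mixture
#' of cubic, orthorhombic, monoclinic, triclinic and hexagonal cells with
#' lengths in `len_range`.  An optional cluster mode adds `cluster_n`
#' near-identical monoclinic cells around a short axis of about
#' `cluster_a` angstroms, emulating the heavily redeposited benchmark
#' structures that dominate single pixels of real parameter maps.
#'
#' @param n number of cells in the random mixture.
#' @param seed integer seed.
#' @param families character subset of
#'   `c("cubic", "orthorhombic", "monoclinic", "triclinic", "hexagonal")`.
#' @param len_range cell-edge range in angstroms.
#' @param cluster_n number of additional near-identical cells (0 disables).
#' @param cluster_a short axis of the cluster cells (angstroms).
#' @return Data frame with columns `id, a, b, c, alpha, beta, gamma,
#'   family`, validated as a cell table (see [validate_cell_table()]).
#' @export
gen_cell_table <- function(n = 100L, seed = NULL,
                           families = c("cubic", "orthorhombic",
                                        "monoclinic", "triclinic",
                                        "hexagonal"),
                           len_range = c(3, 20),
                           cluster_n = 0L, cluster_a = 3.5) {
  families <- match.arg(families, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  draw_len <- function(k) stats::runif(k, len_range[1], len_range[2])
  rows <- lapply(seq_len(n), function(i) {
    fam <- sample(families, 1L)
    l <- sort(draw_len(3))
    row <- switch(fam,
      cubic = c(l[1], l[1], l[1], 90, 90, 90),
      orthorhombic = c(l, 90, 90, 90),
      monoclinic = c(l, 90, stats::runif(1, 95, 130), 90),
      hexagonal = c(l[1], l[1], l[2], 90, 90, 120),
      triclinic = {
        repeat {
          ang <- stats::runif(3, 70, 115)
          ca <- cospi(ang / 180)
          g <- 1 - sum(ca^2) + 2 * prod(ca)
          if (g > 1e-6) break
        }
        c(l, ang)
      })
    data.frame(id = sprintf("syn%05d", i), a = row[1], b = row[2],
               c = row[3], alpha = row[4], beta = row[5], gamma = row[6],
               family = fam, stringsAsFactors = FALSE)
  })
  if (cluster_n > 0L) {
    rows <- c(rows, lapply(seq_len(cluster_n), function(i) {
      data.frame(id = sprintf("clu%05d", i),
                 a = cluster_a + stats::rnorm(1, 0, 0.002),
                 b = cluster_a * 1.72 + stats::rnorm(1, 0, 0.002),
                 c = cluster_a * 3.4 + stats::rnorm(1, 0, 0.002),
                 alpha = 90, beta = 105 + stats::rnorm(1, 0, 0.01),
                 gamma = 90, family = "monoclinic_cluster",
                 stringsAsFactors = FALSE)
    }))
  }
  validate_cell_table(do.call(rbind, rows))
}
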