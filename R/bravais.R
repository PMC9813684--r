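# Bravais classification in the quotient triangle.  The five planar Bravais
# classes partition QT: tp (square) is the vertex (0,0), hp (hexagonal) the
# vertex (0,1), op (primitive rectangular) the open horizontal edge, oc
# (centred rectangular) the open vertical edge and open hypotenuse, and mp
# (oblique) the interior.

.bravais_levels <- c("tp", "hp", "op", "oc", "mp")

#' Bravais class of a projected invariant
#'
#' Nearest-subspace test in QT Euclidean distance with an explicit
#' tolerance.  Vertices take precedence over edges (a point within `tol` of
#' (0,0) is `tp` even though it is also near two edges), edges over the
#' interior.  The default `tol = 1e-9` is meant for exact synthetic input;
#' classifying experimental cells requires opting into a larger tolerance,
#' because near-symmetric lattices are deliberately not snapped.
#'
#' @param pi_ a `"projected_invariant"` (or numeric `c(x, y)`).
#' @param tol non-negative classification tolerance (QT distance).
#' @return One of `"tp"`, `"hp"`, `"op"`, `"oc"`, `"mp"`, with the
#'   tolerance attached as attribute `"tol"`.
#' @examples
#' bravais_class(projected_invariant_values(0, 0))    # "tp"
#' bravais_class(projected_invariant_values(0.2, 0.3))  # "mp"
#' @export
bravais_class <- function(pi_, tol = 1e-9) {
  xy <- .pi_xy(pi_)
  stopifnot(tol >= 0)
  x <- xy[1]; y <- xy[2]
  label <-
    if (sqrt(x^2 + y^2) <= tol) "tp"
    else if (sqrt(x^2 + (y - 1)^2) <= tol) "hp"
    else if (y <= tol) "op"
    else if (x <= tol || (1 - x - y) / sqrt(2) <= tol) "oc"
    else "mp"
  structure(label, tol = tol)
}

#' Tally Bravais labels
#'
#' @param labels character vector of Bravais labels (as from
#'   [bravais_class()]).
#' @return A data frame with columns `class`, `n`, `fraction`, one row per
#'   class present, ordered tp, hp, op, oc, mp; zero rows for empty input.
#' @export
class_counts <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) == 0)
    return(data.frame(class = character(), n = integer(),
                      fraction = numeric()))
  tab <- table(factor(labels, levels = .bravais_levels))
  tab <- tab[tab > 0]
  data.frame(class = names(tab), n = as.integer(tab),
             fraction = as.integer(tab) / length(labels),
             row.names = NULL)
}
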