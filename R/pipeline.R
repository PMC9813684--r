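# Batch mapping pipeline: ingest tables of unit cells, extract the three 2D
# sublattices of each 3D cell, run the reduction/invariant chain on every
# sublattice, and summarise the results as heat maps and reports.

#' Read a cell table from delimited text
#'
#' Accepts comma- or tab-separated text with header `id,a,b,gamma` (2D
#' cells) or `id,a,b,c,alpha,beta,gamma` (3D cells).  Lengths in angstroms,
#' angles in degrees, '.' decimal separator.  Rows failing validation are
#' dropped with a warning and recorded in the `"skipped"` attribute.
#'
#' @param path path to the delimited file.
#' @return A data frame of validated rows with attributes `"cell_dim"`
#'   (2 or 3) and `"skipped"` (character vector of dropped ids).
#' @export
read_cell_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_cell_table(df)
}

#' @rdname read_cell_table
#' @param df a data frame already holding the columns above.
#' @export
validate_cell_table <- function(df) {
  cols3 <- c("a", "b", "c", "alpha", "beta", "gamma")
  cols2 <- c("a", "b", "gamma")
  dim <- if (all(cols3 %in% names(df))) 3L
         else if (all(cols2 %in% names(df))) 2L
         else stop("cell table needs columns id,a,b,gamma or ",
                   "id,a,b,c,alpha,beta,gamma", call. = FALSE)
  if (is.null(df$id)) df$id <- as.character(seq_len(nrow(df)))
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("cell table ids must be unique", call. = FALSE)
  ok <- vapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    !inherits(try(
      if (dim == 3L)
        cell3d(r$a, r$b, r$c, r$alpha, r$beta, r$gamma, id = r$id)
      else cell2d(r$a, r$b, r$gamma),
      silent = TRUE), "try-error")
  }, logical(1))
  skipped <- df$id[!ok]
  if (length(skipped))
    warning(sprintf("skipped %d invalid cell row(s): %s", length(skipped),
                    paste(utils::head(skipped, 5), collapse = ", ")))
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cell_dim") <- dim
  attr(out, "skipped") <- skipped
  out
}

#' Extract the three 2D sublattices of a 3D cell
#'
#' For basis vectors v1, v2, v3 of the cell, the three planar lattices are
#' spanned by the ordered pairs {v2, v3}, {v1, v3}, {v1, v2}, i.e. the 2D
#' cells `(b, c, alpha)`, `(a, c, beta)`, `(a, b, gamma)`.  Downstream
#' embedding places the first vector of each pair on the +x axis with the
#' second in the upper half-plane, which fixes each sublattice's chirality
#' deterministically.
#'
#' @param cell a [cell3d()] object.
#' @return Named list of three [cell2d()] objects (`v2v3`, `v1v3`, `v1v2`).
#' @export
extract_sublattices <- function(cell) {
  stopifnot(inherits(cell, "cell3d"))
  list(v2v3 = cell2d(cell$b, cell$c, cell$alpha),
       v1v3 = cell2d(cell$a, cell$c, cell$beta),
       v1v2 = cell2d(cell$a, cell$b, cell$gamma))
}

#' Map a cell table to per-sublattice invariant records
#'
#' Runs the full chain (Selling reduction, root invariant, sign, projected
#' invariant, Bravais label, spherical coordinates) for every 2D lattice in
#' the table: one record per 2D row, three per 3D row.  Row-level failures
#' are skipped with a warning; the run continues.  Output is deterministic
#' given the table order.
#'
#' @param table a data frame as returned by [read_cell_table()] /
#'   [validate_cell_table()] (raw data frames are validated first).
#' @param sym_tol mirror-symmetry and Bravais tolerance (see
#'   [lattice_sign()]).
#' @return A data frame with one row per sublattice: `id`, `sublattice`,
#'   conorms `p12,p01,p02`, reduced cell `red_a,red_b,red_gamma`, root
#'   invariant `r12,r01,r02`, `sign`, `sigma`, QT coordinates `x,y`,
#'   `bravais`, `lat`, `lon` (`NA` at the poles).
#' @export
map_table <- function(table, sym_tol = 1e-9) {
  if (is.null(attr(table, "cell_dim"))) table <- validate_cell_table(table)
  dim <- attr(table, "cell_dim")
  rec <- vector("list", nrow(table) * if (dim == 3L) 3L else 1L)
  k <- 0L
  for (i in seq_len(nrow(table))) {
    r <- table[i, ]
    subs <- if (dim == 3L)
      extract_sublattices(cell3d(r$a, r$b, r$c, r$alpha, r$beta, r$gamma,
                                 id = r$id))
    else list(v1v2 = cell2d(r$a, r$b, r$gamma))
    for (nm in names(subs)) {
      k <- k + 1L
      res <- try(lattice_invariants(cell_to_basis(subs[[nm]]),
                                    sym_tol = sym_tol), silent = TRUE)
      if (inherits(res, "try-error")) {
        warning(sprintf("skipped sublattice %s of cell %s", nm, r$id))
        next
      }
      rec[[k]] <- data.frame(
        id = r$id, sublattice = nm,
        p12 = res$superbase$p[["p12"]], p01 = res$superbase$p[["p01"]],
        p02 = res$superbase$p[["p02"]],
        red_a = res$cell$a, red_b = res$cell$b, red_gamma = res$cell$gamma,
        r12 = res$ri[[1]], r01 = res$ri[[2]], r02 = res$ri[[3]],
        sign = res$sign, sigma = res$sigma,
        x = res$pi$x, y = res$pi$y,
        bravais = as.character(res$bravais),
        lat = res$sphere$latitude,
        lon = if (res$sphere$defined_longitude) res$sphere$longitude
              else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rec[!vapply(rec, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Parameter maps and histograms per Bravais family
#'
#' Recovers the family-specific cell parameters from the root invariants of
#' classified records and bins them:
#' \itemize{
#'   \item `op` (primitive rectangular, RI = (0, a, b)): heat map of the
#'     primitive cell sides `(a, b) = (r01, r02)`;
#'   \item `oc` (centred rectangular, conventional cell `2a x 2b`): heat map
#'     of the half-cell sides, inverted from the repeated root component
#'     (`a = r/sqrt(2)` from the repeated pair, `b = sqrt(r_odd^2 + a^2)`);
#'   \item `tp` (square): histogram of the minimum inter-point distance
#'     `a = r01`;
#'   \item `hp` (hexagonal): histogram of `a = r12 sqrt(2)`.
#' }
#'
#' @param records data frame from [map_table()].
#' @param pixel bin size in angstroms for heat maps and histograms.
#' @return List with heat grids `op`, `oc` and histogram data frames `tp`,
#'   `hp` (columns `mid`, `count`).
#' @export
parameter_maps <- function(records, pixel = 0.1) {
  stopifnot(is.data.frame(records))
  f <- function(lab) records[records$bravais == lab, , drop = FALSE]
  op <- f("op"); oc <- f("oc"); tp <- f("tp"); hp <- f("hp")

  oc_ab <- if (nrow(oc)) t(vapply(seq_len(nrow(oc)), function(i)
    oc_half_cell(c(oc$r12[i], oc$r01[i], oc$r02[i])),
    numeric(2))) else matrix(numeric(), 0, 2)

  hist_of <- function(v) {
    if (!length(v)) return(data.frame(mid = numeric(), count = integer()))
    nb <- ceiling(max(v) / pixel)
    idx <- .bin_index(v, 0, pixel, nb)
    tab <- table(factor(idx, levels = seq_len(nb)))
    data.frame(mid = (seq_len(nb) - 0.5) * pixel, count = as.integer(tab))
  }

  list(op = bin_params(op$r01, op$r02, pixel = pixel),
       oc = bin_params(oc_ab[, 1], oc_ab[, 2], pixel = pixel),
       tp = hist_of(tp$r01),
       hp = hist_of(hp$r12 * sqrt(2)))
}

#' Half-cell sides of a centred rectangular lattice from its root invariant
#'
#' A centred rectangular lattice with conventional cell `2a x 2b` has root
#' invariant `(sqrt(b^2 - a^2), a sqrt(2), a sqrt(2))` up to ordering: two
#' components equal `a sqrt(2)` and the odd one is `sqrt(b^2 - a^2)`.  This
#' inverts that relation, picking the branch from whichever pair of
#' components is closer.
#'
#' @param ri root invariant (numeric triple, sorted ascending).
#' @return Numeric `c(a, b)` of the conventional half-cell (angstroms).
#' @export
oc_half_cell <- function(ri) {
  r <- as.numeric(ri)
  stopifnot(length(r) == 3L)
  if (abs(r[2] - r[3]) <= abs(r[2] - r[1])) {  # r01 = r02: b < a sqrt(3)
    a <- (r[2] + r[3]) / (2 * sqrt(2)); b <- sqrt(r[1]^2 + a^2)
  } else {                                     # r12 = r01: b > a sqrt(3)
    a <- (r[1] + r[2]) / (2 * sqrt(2)); b <- sqrt(r[3]^2 + a^2)
  }
  c(a = a, b = b)
}

#' Figure-style text report of a mapped table
#'
#' Mirrors the caption taxonomy of the published CSD maps: record counts per
#' chirality-sign filter, per longitude hemisphere, for oblique-only
#' subsets, and per Bravais class, so synthetic runs can be compared
#' structurally with the published figures.
#'
#' @param records data frame from [map_table()].
#' @return An object of class `"figure_report"`: list with `counts` (named
#'   integer vector), `bravais` (from [class_counts()]) and `text`
#'   (character lines).
#' @export
figure_report <- function(records) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  s <- if (n) records$sign else integer()
  lon <- if (n) records$lon else numeric()
  obl <- if (n) records$bravais == "mp" else logical()
  # hemisphere filters as in the published captions: west mu in (-180, 0]
  # (wrap point 180 counted west), east mu in [0, 180); they share mu = 0
  east <- !is.na(lon) & lon >= 0 & lon < 180
  west <- !is.na(lon) & (lon <= 0 | lon == 180)
  counts <- c(total = n,
              `sign>0` = sum(s > 0), `sign>=0` = sum(s >= 0),
              `sign<0` = sum(s < 0), `sign<=0` = sum(s <= 0),
              `sign=0` = sum(s == 0),
              oblique = sum(obl),
              `oblique sign>0` = sum(obl & s > 0),
              `oblique sign<0` = sum(obl & s < 0),
              `east mu in [0,180)` = sum(east),
              `west mu in (-180,0]` = sum(west),
              `pole (undefined mu)` = sum(is.na(lon)))
  cc <- class_counts(if (n) records$bravais else character())
  text <- c("lattice map report",
            sprintf("  %-28s %d", names(counts), counts),
            "  Bravais classes:",
            if (nrow(cc)) sprintf("    %-4s %7d  (%.3f)", cc$class, cc$n,
                                  cc$fraction) else "    (none)")
  structure(list(counts = counts, bravais = cc, text = text),
            class = "figure_report")
}

#' @export
print.figure_report <- function(x, ...) {
  writeLines(x$text)
  invisible(x)
}
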