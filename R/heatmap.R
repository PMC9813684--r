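# Heat grids: half-open rectangular binning of invariant coordinates for the
# quotient-triangle, quotient-square, spherical and parameter-plane maps.

.heat_grid <- function(counts, xedges, yedges, domain, pixel) {
  structure(list(domain = domain, pixel = pixel, counts = counts,
                 xedges = xedges, yedges = yedges),
            class = "heat_grid")
}

#' @export
print.heat_grid <- function(x, ...) {
  cat(sprintf("<heat_grid>  domain %s, %d x %d bins of %s, %d points\n",
              x$domain, nrow(x$counts), ncol(x$counts),
              paste(signif(x$pixel, 4), collapse = " x "),
              sum(x$counts)))
  invisible(x)
}

# half-open binning of v into [edges[k], edges[k+1]); the final upper edge is
# closed so that the domain maximum is kept
.bin_index <- function(v, lo, pixel, nbin) {
  k <- floor((v - lo) / pixel) + 1
  pmin(pmax(k, 1L), nbin)
}

#' Bin projected invariants into a quotient-triangle or quotient-square grid
#'
#' Pixels are half-open `[k p, (k+1) p)` squares of side `pixel` covering
#' the unit square; points on the hypotenuse `x + y = 1` fall into their
#' containing bin without special treatment.  For `domain = "qs"` the two
#' chirality copies are folded into the quotient square: points with
#' negative sign are reflected through the enantiomorph pairing
#' `(x, y) -> (1 - y, 1 - x)`.
#'
#' @param points data frame (or matrix) with columns `x`, `y` and, for
#'   `domain = "qs"`, `sign`.
#' @param pixel bin side length, default 0.005.
#' @param domain `"qt"` (isometry classes) or `"qs"` (rigid-motion classes).
#' @return A `"heat_grid"` whose counts sum to the number of points.
#' @export
bin_qt <- function(points, pixel = 0.005, domain = c("qt", "qs")) {
  domain <- match.arg(domain)
  points <- as.data.frame(points)
  x <- points$x; y <- points$y
  if (length(x) && (anyNA(x) || anyNA(y) || any(x < 0 | y < 0 | x > 1 |
                                                y > 1 | x + y > 1 + 1e-9)))
    stop("points outside the quotient triangle", call. = FALSE)
  if (domain == "qs") {
    if (is.null(points$sign))
      stop("domain 'qs' needs a sign column", call. = FALSE)
    neg <- points$sign < 0
    xn <- ifelse(neg, 1 - y, x)
    yn <- ifelse(neg, 1 - x, y)
    x <- xn; y <- yn
  }
  nbin <- ceiling(1 / pixel)
  edges <- seq(0, by = pixel, length.out = nbin + 1)
  counts <- matrix(0L, nbin, nbin)
  if (length(x)) {
    ix <- .bin_index(x, 0, pixel, nbin)
    iy <- .bin_index(y, 0, pixel, nbin)
    tab <- table(factor(ix, levels = seq_len(nbin)),
                 factor(iy, levels = seq_len(nbin)))
    counts <- matrix(as.integer(tab), nbin, nbin)
  }
  .heat_grid(counts, edges, edges, domain, pixel)
}

#' Bin spherical coordinates into a latitude-longitude grid
#'
#' Curved pixels of `pixel x pixel` degrees, half-open, longitude in
#' (-180, 180] and latitude in [-90, 90]; the top latitude band is closed so
#' the poles are kept, acting as polar caps.  Coordinates with undefined
#' longitude (exact poles) are binned at longitude 0 in their polar cap.
#'
#' @param coords data frame with columns `latitude`, `longitude` (degrees),
#'   or a list of `"sphere_coord"` objects.
#' @param pixel angular bin size in degrees, default 1.
#' @return A `"heat_grid"` with longitude bins as rows, latitude bins as
#'   columns.
#' @export
bin_sphere <- function(coords, pixel = 1) {
  if (is.list(coords) && length(coords) && inherits(coords[[1]], "sphere_coord"))
    coords <- data.frame(
      latitude = vapply(coords, `[[`, numeric(1), "latitude"),
      longitude = vapply(coords, function(s)
        if (s$defined_longitude) s$longitude else 0, numeric(1)))
  coords <- as.data.frame(coords)
  lat <- coords$latitude
  lon <- ifelse(is.na(coords$longitude), 0, coords$longitude)
  if (length(lat) && (any(abs(lat) > 90) || any(lon <= -180 | lon > 180)))
    stop("coordinates outside the sphere parameterization", call. = FALSE)
  nlon <- ceiling(360 / pixel); nlat <- ceiling(180 / pixel)
  counts <- matrix(0L, nlon, nlat)
  if (length(lat)) {
    # longitude half-open on the left: (-180, -180 + p], ..., so shift the
    # parameterization: bin k covers (-180 + (k-1) p, -180 + k p]
    ilon <- pmin(pmax(ceiling((lon + 180) / pixel), 1L), nlon)
    ilat <- .bin_index(lat, -90, pixel, nlat)
    tab <- table(factor(ilon, levels = seq_len(nlon)),
                 factor(ilat, levels = seq_len(nlat)))
    counts <- matrix(as.integer(tab), nlon, nlat)
  }
  .heat_grid(counts, seq(-180, by = pixel, length.out = nlon + 1),
             seq(-90, by = pixel, length.out = nlat + 1),
             "sphere", pixel)
}

#' Bin parameter pairs (a, b) into an angstrom grid
#'
#' Used for the rectangular and centred-rectangular parameter maps.
#'
#' @param a,b numeric vectors of side lengths (angstroms).
#' @param pixel bin side (angstroms), default 0.1.
#' @param lim upper limit of both axes; defaults to the data maximum rounded
#'   up to a pixel.
#' @return A `"heat_grid"` with domain `"params"`.
#' @export
bin_params <- function(a, b, pixel = 0.1, lim = NULL) {
  stopifnot(length(a) == length(b))
  if (is.null(lim))
    lim <- if (length(a)) pixel * ceiling(max(a, b) / pixel) else pixel
  nbin <- max(1L, ceiling(lim / pixel))
  counts <- matrix(0L, nbin, nbin)
  if (length(a)) {
    ia <- .bin_index(a, 0, pixel, nbin)
    ib <- .bin_index(b, 0, pixel, nbin)
    tab <- table(factor(ia, levels = seq_len(nbin)),
                 factor(ib, levels = seq_len(nbin)))
    counts <- matrix(as.integer(tab), nbin, nbin)
  }
  .heat_grid(counts, seq(0, by = pixel, length.out = nbin + 1),
             seq(0, by = pixel, length.out = nbin + 1),
             "params", pixel)
}

#' Write a heat grid as plain text
#'
#' The count matrix round-trips bit-exactly through
#' [write_heat_grid()]/[read_heat_grid()]; header comment lines carry the
#' domain, pixel size and edge origins.
#'
#' @param grid a `"heat_grid"`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_heat_grid <- function(grid, path) {
  stopifnot(inherits(grid, "heat_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# heat_grid domain=%s pixel=%.17g", grid$domain, grid$pixel),
    sprintf("# xorigin=%.17g yorigin=%.17g nx=%d ny=%d",
            grid$xedges[1], grid$yedges[1],
            nrow(grid$counts), ncol(grid$counts))), con)
  utils::write.table(grid$counts, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_heat_grid
#' @export
read_heat_grid <- function(path) {
  hdr <- readLines(path, n = 2L)
  m1 <- regmatches(hdr[1], regexec(
    "domain=(\\S+) pixel=(\\S+)", hdr[1]))[[1]]
  m2 <- regmatches(hdr[2], regexec(
    "xorigin=(\\S+) yorigin=(\\S+) nx=(\\d+) ny=(\\d+)", hdr[2]))[[1]]
  domain <- m1[2]; pixel <- as.numeric(m1[3])
  xo <- as.numeric(m2[2]); yo <- as.numeric(m2[3])
  nx <- as.integer(m2[4]); ny <- as.integer(m2[5])
  counts <- as.matrix(utils::read.table(path, sep = ",", skip = 2L))
  dimnames(counts) <- NULL
  storage.mode(counts) <- "integer"
  stopifnot(nrow(counts) == nx, ncol(counts) == ny)
  .heat_grid(counts, seq(xo, by = pixel, length.out = nx + 1),
             seq(yo, by = pixel, length.out = ny + 1), domain, pixel)
}

#' Render a heat grid to an image and an exact count dump
#'
#' The CSV dump (via [write_heat_grid()]) is the bit-exact interface; the
#' image is advisory.  The logarithmic scale colours by `log10(1 + count)`,
#' so empty bins map to colour value 0.
#'
#' @param grid a `"heat_grid"`.
#' @param file output stem; writes `<file>_counts.csv` and `<file>.png`.
#' @param scale `"log"` or `"linear"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
render_heat_grid <- function(grid, file, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  stopifnot(inherits(grid, "heat_grid"))
  csv <- paste0(file, "_counts.csv")
  png <- paste0(file, ".png")
  write_heat_grid(grid, csv)
  z <- grid$counts
  if (scale == "log") z <- log10(1 + z)
  if (all(z == 0)) warning("empty heat grid: rendering a blank image")
  grDevices::png(png, width = 800, height = 800)
  on.exit(grDevices::dev.off())
  graphics::image(x = grid$xedges, y = grid$yedges, z = z,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  useRaster = TRUE, xlab = "x", ylab = "y",
                  main = sprintf("%s heat map (%s scale)", grid$domain, scale))
  invisible(c(counts = csv, image = png))
}
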