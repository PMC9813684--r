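# Independent oracles used to cross-check the Selling reduction.  Both work
# directly from the basis Gram matrix and never call selling_reduce().

# all 2x2 integer matrices with entries in [-N, N] and determinant +1 or -1
unimodular_pool <- function(N = 10L) {
  g <- expand.grid(a = -N:N, b = -N:N, c = -N:N, d = -N:N)
  as.matrix(g[abs(g$a * g$d - g$b * g$c) == 1L, ])
}

# bounded brute force: over every re-basing (w1, w2) = M (v1, v2) in the
# pool, find the superbase minimizing |w0|^2 + |w1|^2 + |w2|^2 and return
# its sorted conorm triple
brute_force_conorms <- function(basis, pool) {
  g11 <- sum(basis$v1^2); g22 <- sum(basis$v2^2)
  g12 <- sum(basis$v1 * basis$v2)
  a <- pool[, 1]; b <- pool[, 2]; cc <- pool[, 3]; d <- pool[, 4]
  n1 <- a^2 * g11 + 2 * a * b * g12 + b^2 * g22        # |w1|^2
  n2 <- cc^2 * g11 + 2 * cc * d * g12 + d^2 * g22      # |w2|^2
  w12 <- a * cc * g11 + (a * d + b * cc) * g12 + b * d * g22  # w1.w2
  tot <- 2 * (n1 + n2 + w12)                           # norm sum of superbase
  i <- which.min(tot)
  unname(sort(c(-w12[i], n1[i] + w12[i], n2[i] + w12[i])))  # (p12, p01, p02)
}

# Lagrange-Gauss reduction: shortest-vector basis, then flip the second
# vector to make the pair non-acute; returns the sorted conorm triple of
# the associated superbase
lagrange_gauss_conorms <- function(basis) {
  v1 <- basis$v1; v2 <- basis$v2
  repeat {
    if (sum(v1^2) > sum(v2^2)) { tmp <- v1; v1 <- v2; v2 <- tmp }
    m <- round(sum(v1 * v2) / sum(v1^2))
    w <- v2 - m * v1
    # apply only strictly shortening steps; ties (e.g. hexagonal lattices,
    # |ratio| = 1/2) would otherwise oscillate forever
    if (sum(w^2) >= sum(v2^2) * (1 - 1e-12)) break
    v2 <- w
  }
  if (sum(v1^2) > sum(v2^2)) { tmp <- v1; v1 <- v2; v2 <- tmp }
  if (sum(v1 * v2) > 0) v2 <- -v2
  unname(sort(c(-sum(v1 * v2),
                sum(v1^2) + sum(v1 * v2),
                sum(v2^2) + sum(v1 * v2))))
}

# run the full invariant chain on generator records and collect a
# map_table-style data frame
records_from_lattices <- function(recs, sym_tol = 1e-9) {
  do.call(rbind, lapply(seq_along(recs), function(i) {
    res <- lattice_invariants(recs[[i]]$basis, sym_tol = sym_tol)
    data.frame(id = as.character(i), sublattice = "v1v2",
               r12 = res$ri[[1]], r01 = res$ri[[2]], r02 = res$ri[[3]],
               sign = res$sign, sigma = res$sigma,
               x = res$pi$x, y = res$pi$y,
               bravais = as.character(res$bravais),
               lat = res$sphere$latitude,
               lon = if (res$sphere$defined_longitude) res$sphere$longitude
                     else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
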