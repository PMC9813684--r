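# Root invariants, chirality signs, projected invariants and the derived
# distances.

test_that("root_invariant reproduces the family closed forms", {
  ri <- root_invariant(selling_reduce(basis2d(c(1, 0), c(0, 1))))
  expect_equal(unname(unclass(ri)), c(0, 1, 1))

  ri <- root_invariant(selling_reduce(cell_to_basis(cell2d(1, 1, 120))))
  expect_equal(unname(unclass(ri)), rep(1 / sqrt(2), 3), tolerance = 1e-12)

  # centred rectangular, conventional cell 2x1 by 2x2 (half-cell a=1, b=2):
  # superbase (2a,0), (-a,b), (-a,-b) has conorms (2a^2, 2a^2, b^2 - a^2)
  ri <- root_invariant(selling_reduce(basis2d(c(2, 0), c(-1, 2))))
  expect_equal(unname(unclass(ri)), c(sqrt(2), sqrt(2), sqrt(3)),
               tolerance = 1e-12)
})

test_that("lattice_sign is 0 for achiral lattices and tracks orientation", {
  expect_identical(lattice_sign(selling_reduce(basis2d(c(2, 0), c(0, 3)))), 0L)
  expect_identical(lattice_sign(selling_reduce(basis2d(c(1, 0), c(0, 1)))), 0L)

  sb <- selling_reduce(basis2d(c(1.9, 0), c(-0.18, 3.63)))
  expect_identical(lattice_sign(sb), 1L)
  sb <- selling_reduce(basis2d(c(1.9, 0), c(-0.18, -3.63)))
  expect_identical(lattice_sign(sb), -1L)
})

test_that("size is the component sum and scales linearly", {
  expect_equal(ri_size(root_invariant_values(0, 1, 1)), 2)
  expect_equal(ri_size(rep(1 / sqrt(2), 3)), 3 / sqrt(2))
  r <- c(0.2, 0.5, 0.9)
  expect_equal(ri_size(3.7 * r), 3.7 * ri_size(r))
})

test_that("projected invariants hit the printed anchors", {
  hx <- lattice_invariants(cell_to_basis(cell2d(1, 1, 120)))
  expect_equal(c(hx$pi$x, hx$pi$y), c(0, 1), tolerance = 1e-12)

  sq <- lattice_invariants(basis2d(c(1, 0), c(0, 1)))
  expect_equal(c(sq$pi$x, sq$pi$y), c(0, 0))

  # the inversely designed lattice whose invariant is near the QT incentre
  inc <- lattice_invariants(basis2d(c(1.9, 0), c(-0.18, 3.63)))
  t <- qt_incentre()
  expect_lt(abs(inc$pi$x - t), 0.01)
  expect_lt(abs(inc$pi$y - t), 0.01)

  # rectangular a=1, b=3: RI = (0, a, b) so x = (b-a)/(a+b), y = 0
  rc <- lattice_invariants(basis2d(c(1, 0), c(0, 3)))
  expect_equal(c(rc$pi$x, rc$pi$y), c(0.5, 0))
})

test_that("projection is scale-invariant and RI scale-equivariant", {
  set.seed(31)
  for (r in gen_lattices("mixed", n = 50, scramble = FALSE)) {
    c_ <- runif(1, 0.1, 10)
    ri1 <- root_invariant(selling_reduce(r$basis))
    ri2 <- root_invariant(selling_reduce(
      basis2d(c_ * r$basis$v1, c_ * r$basis$v2)))
    expect_equal(unname(unclass(ri2)), c_ * unname(unclass(ri1)),
                 tolerance = 1e-9)
    p1 <- projected_invariant(ri1); p2 <- projected_invariant(ri2)
    expect_equal(c(p1$x, p1$y), c(p2$x, p2$y), tolerance = 1e-9)
  }
})

test_that("oriented invariants are complete surrogates: re-basing fixes RI,
           reflection flips only the sign", {
  set.seed(97)
  recs <- gen_lattices("mixed", n = 500, scramble = FALSE)
  for (r in recs) {
    sb0 <- selling_reduce(r$basis)
    ri0 <- unname(sqrt(sb0$p)); s0 <- lattice_sign(sb0)
    for (k in 1:10) {
      M <- random_unimodular(sample(1:5, 1))
      w1 <- M[1, 1] * r$basis$v1 + M[1, 2] * r$basis$v2
      w2 <- M[2, 1] * r$basis$v1 + M[2, 2] * r$basis$v2
      th <- runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      sb <- selling_reduce(basis2d(R %*% w1, R %*% w2))
      # conorms agree to machine precision; zero/tied roots carry the
      # sqrt-amplified noise floor that scales with sigma, so roots are compared at 1e-6 and
      # the mirror test uses a tolerance above that floor
      expect_equal(unname(sb$p), unname(sb0$p), tolerance = 1e-9)
      expect_equal(unname(sqrt(sb$p)), ri0, tolerance = 1e-6)
      expect_identical(lattice_sign(sb, tol = 1e-7), s0)
    }
    # reflection: same RI, opposite sign (when chiral)
    sbm <- selling_reduce(basis2d(r$basis$v1 * c(1, -1),
                                  r$basis$v2 * c(1, -1)))
    expect_equal(unname(sqrt(sbm$p)), ri0, tolerance = 1e-9)
    expect_identical(lattice_sign(sbm), -s0)
  }
})

test_that("every lattice projects into the quotient triangle", {
  set.seed(12)
  for (r in gen_lattices("mixed", n = 2000)) {
    li <- lattice_invariants(r$basis, sym_tol = 1e-7)
    x <- li$pi$x; y <- li$pi$y
    expect_gte(x, 0); expect_lt(x, 1)
    expect_gte(y, 0); expect_lte(y, 1)
    expect_lte(x + y, 1 + 1e-12)
  }
  # on exact (unscrambled) bases the boundary structure is sharp:
  # hypotenuse iff r12 = r01, boundary iff achiral
  for (r in gen_lattices("mixed", n = 500, scramble = FALSE)) {
    li <- lattice_invariants(r$basis)
    x <- li$pi$x; y <- li$pi$y
    hyp <- abs(1 - x - y) < 1e-12
    expect_identical(hyp, abs(li$ri[[1]] - li$ri[[2]]) < 1e-12 * li$sigma)
    on_bd <- x < 1e-9 || y < 1e-9 || 1 - x - y < 1e-9
    expect_identical(li$sign == 0L, on_bd)
  }
})

test_that("small basis perturbations move RI continuously (no jumps)", {
  set.seed(61)
  eps <- 1e-4
  recs <- gen_lattices("mixed", n = 1000)
  C_emp <- numeric(length(recs))
  for (i in seq_along(recs)) {
    b <- recs[[i]]$basis
    d <- matrix(runif(4, -eps, eps), 2)
    b2 <- basis2d(b$v1 + d[, 1], b$v2 + d[, 2])
    dist <- ri_distance(root_invariant(selling_reduce(b)),
                        root_invariant(selling_reduce(b2)))
    C_emp[i] <- dist / eps
    # each conorm moves by at most ~ eps * (|v_i| + |v_j|), and
    # |sqrt(p') - sqrt(p)| <= sqrt(|p' - p|), so a safe per-case bound is
    nrm <- sqrt(max(sum(b$v1^2), sum(b$v2^2), sum((b$v1 + b$v2)^2)))
    expect_lte(dist, 2 * sqrt(eps * (2 * nrm + 2 * eps)))
  }
  expect_true(all(is.finite(C_emp)))
})

test_that("quadratic invariant matches reduced metric tensors", {
  qi <- quadratic_invariant(reduced_cell(selling_reduce(
    basis2d(c(1, 0), c(0, 1)))))
  expect_equal(unname(unclass(qi)), c(1, 0, 1))

  # the lattice of the form Q = 9x^2 - 6xy + 5y^2, basis (3,0), (-1,2):
  # that basis is not non-acute reduced (|v1| > |v2|); its reduced metric
  # tensor is (5, -2, 8) (same Gram determinant 36), so QI = (s5, s2, s8)
  qi <- quadratic_invariant(reduced_cell(selling_reduce(
    basis2d(c(3, 0), c(-1, 2)))))
  expect_equal(unname(unclass(qi)), c(sqrt(5), sqrt(2), sqrt(8)),
               tolerance = 1e-12)

  qi <- quadratic_invariant(reduced_cell(selling_reduce(
    cell_to_basis(cell2d(1, 1, 120)))))
  expect_equal(unname(unclass(qi)), c(1, 1 / sqrt(2), 1), tolerance = 1e-12)
})

test_that("ri_distance is a symmetric L-infinity metric", {
  expect_equal(ri_distance(c(0, 1, 1), c(0, 1, 1)), 0)
  expect_equal(ri_distance(c(0, 1, 1), c(0, 1, 2)), 1)
  set.seed(3)
  for (i in 1:100) {
    a <- sort(runif(3, 0.1, 2)); b <- sort(runif(3, 0.1, 2))
    expect_equal(ri_distance(a, b), ri_distance(b, a))
    expect_equal(ri_distance(a, b), max(abs(a - b)))
  }
})

test_that("dissymmetry vanishes exactly on each symmetry subspace", {
  d <- dissymmetry(projected_invariant_values(0, 0))
  expect_equal(unname(d["tp"]), 0)

  d <- dissymmetry(projected_invariant_values(0.5, 0))
  expect_equal(unname(d["op"]), 0)
  # distance to {x=0} u {x+y=1}: min(0.5, 0.5/sqrt(2)) by plane geometry
  expect_equal(unname(d["oc"]), 0.5 / sqrt(2))

  d <- dissymmetry(projected_invariant_values(0.2, 0.3, sign = 1))
  expect_true(all(d > 0))

  # brute-force check against dense sampling of the subspaces; points are
  # kept away from the subspaces so the grid oracle resolves the minimum
  set.seed(8)
  dense <- seq(0, 1, length.out = 20001)
  for (i in 1:20) {
    x <- runif(1, 0.05, 0.45); y <- runif(1, 0.05, 0.45)
    d <- dissymmetry(projected_invariant_values(x, y, sign = 1))
    expect_equal(unname(d["op"]),
                 min(sqrt((x - dense)^2 + y^2)), tolerance = 1e-5)
    expect_equal(unname(d["oc"]),
                 min(sqrt(x^2 + (y - dense)^2),
                     sqrt((x - dense)^2 + (y - (1 - dense))^2)),
                 tolerance = 1e-5)
  }
})
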