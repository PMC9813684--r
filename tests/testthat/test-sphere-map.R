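# Spherical latitude/longitude map of the quotient triangle.

test_that("bearing from the incentre matches known directions", {
  t <- qt_incentre()
  expect_equal(qt_bearing(c(0, 0)), -135)
  expect_equal(qt_bearing(c(t, 0)), -90)
  expect_equal(qt_bearing(qt_greenwich()), 157.5)
  expect_error(qt_bearing(c(t, t)), "incentre")
})

test_that("longitude reproduces the printed anchors", {
  sq <- lattice_invariants(basis2d(c(1, 0), c(0, 1)))
  expect_equal(sq$sphere$longitude, 67.5)

  hx <- lattice_invariants(cell_to_basis(cell2d(1, 1, 120)))
  expect_equal(hx$sphere$longitude, -45)

  # centred rectangular at the hypotenuse midpoint (1/2, 1/2):
  # half-cell a = 1, b = sqrt(33) gives RI = (sqrt(2), sqrt(2), sqrt(32))
  cr <- lattice_invariants(basis2d(c(2, 0), c(-1, sqrt(33))))
  expect_equal(c(cr$pi$x, cr$pi$y), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(cr$sphere$longitude, -112.5)

  # rectangular cell 1 x (2 sqrt(2) - 1): x = 1 - 1/sqrt(2), y = 0
  rc <- lattice_invariants(basis2d(c(1, 0), c(0, 2 * sqrt(2) - 1)))
  expect_equal(rc$pi$x, qt_incentre(), tolerance = 1e-12)
  expect_equal(rc$sphere$longitude, 112.5)

  # Greenwich lattice: centred rectangular with the solved side ratio
  q <- greenwich_ratio()
  gw <- lattice_invariants(basis2d(c(2, 0), c(-1, q)))
  expect_equal(c(gw$pi$x, gw$pi$y), unname(qt_greenwich()),
               tolerance = 1e-9)
  expect_equal(gw$sphere$longitude, 0, tolerance = 1e-7)
})

test_that("longitude wraps half-open with +180 on the segment to (1,0)", {
  t <- qt_incentre()
  # on the open segment from (1, 0) towards the incentre: exactly +180
  mid <- c((1 + t) / 2, t / 2)
  expect_equal(qt_longitude(mid), 180)
  # just either side of the segment: slightly anticlockwise (above) lands
  # just past -180, slightly clockwise (below) just under +180
  hi <- qt_longitude(mid - c(0, 1e-6))
  expect_gt(hi, 179.9); expect_lte(hi, 180)
  lo <- qt_longitude(mid + c(0, 1e-6))
  expect_lt(lo, -179.9)
  expect_gt(lo, -180)
})

test_that("boundary hit lies on the boundary along the incentre ray", {
  t <- qt_incentre()
  expect_equal(qt_boundary_hit(c(0.01, 0.01)), c(0, 0), tolerance = 1e-9)

  # ray through (t, t/2) points straight down: hits (t, 0)
  h <- qt_boundary_hit(c(t, t / 2))
  expect_equal(h, c(t, 0), tolerance = 1e-12)

  set.seed(19)
  for (i in 1:200) {
    repeat {
      x <- runif(1); y <- runif(1, 0, 1 - x)
      if (abs(x - t) + abs(y - t) > 1e-6) break
    }
    h <- qt_boundary_hit(c(x, y))
    on_edge <- min(abs(h[1]), abs(h[2]), abs(1 - h[1] - h[2]))
    expect_lt(on_edge, 1e-12)
    # hit is on the outward ray: collinear and further from the incentre
    d1 <- c(x, y) - c(t, t); d2 <- h - c(t, t)
    expect_equal(d1[1] * d2[2] - d1[2] * d2[1], 0, tolerance = 1e-10)
    expect_gte(sum(d1 * d2), 0)
  }
})

test_that("latitude anchors: equator, poles, and linear interpolation", {
  # mirror-symmetric lattices sit on the equator
  for (b in list(basis2d(c(3, 0), c(0, 5)), basis2d(c(1, 0), c(0, 1)),
                 cell_to_basis(cell2d(2, 2, 120))))
    expect_equal(lattice_invariants(b)$sphere$latitude, 0)

  # the incentre lattice, built by inverse design with sign +1, is the pole
  t <- qt_incentre()
  b <- lattice_from_ri(ri_from_qt(t, t), sign = 1)
  li <- lattice_invariants(b)
  expect_equal(c(li$pi$x, li$pi$y), c(t, t), tolerance = 1e-12)
  expect_equal(li$sphere$latitude, 90)
  expect_false(li$sphere$defined_longitude)

  # midpoint of the incentre-to-boundary segment, sign -1: latitude -45
  hit <- qt_boundary_hit(c(t, t / 2))
  mid <- (c(t, t) + hit) / 2
  p <- projected_invariant_values(mid[1], mid[2], sign = -1)
  expect_equal(qt_latitude(p), -45, tolerance = 1e-12)

  # inconsistent interior point with sign 0 is rejected
  expect_error(qt_latitude(projected_invariant_values(0.3, 0.3, sign = 0)),
               "inconsistent")
})

test_that("latitude decreases linearly and strictly along incentre rays", {
  set.seed(44)
  t <- qt_incentre()
  for (i in 1:20) {
    th <- runif(1, 0, 2 * pi)
    hit <- qt_boundary_hit(c(t + 1e-3 * cos(th), t + 1e-3 * sin(th)))
    s <- seq(0.05, 0.95, by = 0.1)
    phi <- vapply(s, function(si) {
      p <- c(t, t) * (1 - si) + hit * si
      qt_latitude(projected_invariant_values(p[1], p[2], sign = 1))
    }, numeric(1))
    expect_equal(phi, 90 * (1 - s), tolerance = 1e-9)
    expect_true(all(diff(phi) < 0))
  }
})

test_that("the spherical map is injective on sampled oriented invariants", {
  set.seed(77)
  n <- 10000
  x <- runif(n); y <- runif(n) * (1 - x)
  keep <- x > 1e-6 & y > 1e-6 & 1 - x - y > 1e-6 &
    abs(x - qt_incentre()) + abs(y - qt_incentre()) > 1e-6
  x <- x[keep]; y <- y[keep]
  s <- sample(c(-1, 1), length(x), replace = TRUE)
  coords <- vapply(seq_along(x), function(i) {
    sc <- spherical_map(projected_invariant_values(x[i], y[i], s[i]))
    c(sc$latitude, sc$longitude)
  }, numeric(2))
  expect_false(any(duplicated(t(coords))))
})

test_that("reflection keeps the longitude and negates the latitude", {
  set.seed(55)
  for (r in gen_lattices("oblique", n = 50)) {
    li <- lattice_invariants(r$basis)
    lm <- lattice_invariants(basis2d(r$basis$v1 * c(1, -1),
                                     r$basis$v2 * c(1, -1)))
    expect_equal(lm$sphere$longitude, li$sphere$longitude,
                 tolerance = 1e-9)
    expect_equal(lm$sphere$latitude, -li$sphere$latitude,
                 tolerance = 1e-9)
  }
})

test_that("the Greenwich side ratio solves the vertical-edge equation", {
  q <- greenwich_ratio()
  expect_equal(signif(q, 2), 1.1)
  expect_lt(q, sqrt(3))
  # feeding the ratio back through the invariant chain returns G
  ri <- root_invariant(selling_reduce(basis2d(c(2, 0), c(-1, q))))
  p <- projected_invariant(ri)
  expect_equal(c(p$x, p$y), unname(qt_greenwich()), tolerance = 1e-9)
})
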