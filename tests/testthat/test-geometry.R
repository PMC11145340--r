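test_that("axis lengths and orientation recover analytic shapes", {
  # 30 x 10 axis-aligned rectangle: flat, 3:1 aspect
  rect <- region_from_mask(matrix(1L, 10, 30))
  g <- geometric_features(rect)
  expect_equal(g$theta, 0)
  expect_equal(g$Major / g$Minor, 3, tolerance = 0.05)
  expect_equal(g$Area, 300)

  # digital disk r = 15: round, diameter ~ 30
  g2 <- geometric_features(region_from_mask(disk_mask(15L)))
  expect_lt(g2$Ecc, 0.1)
  expect_gt(g2$Ell, 0.95)
  expect_equal(g2$Dia, 30, tolerance = 0.02 * 30)

  # closed form: Area 100 -> equivalent diameter
  expect_equal(sqrt(4 * 100 / pi), 11.28379, tolerance = 1e-5)
  sq <- geometric_features(region_from_mask(matrix(1L, 10, 10)))
  expect_equal(sq$Dia, 11.28379, tolerance = 1e-5)
})

test_that("eccentricity and ellipticity satisfy Ecc = sqrt(1 - Ell^2)", {
  set.seed(7)
  for (k in 1:25) {
    g <- geometric_features(region_from_mask(random_mask(20, 20)))
    expect_equal(g$Ecc, sqrt(1 - g$Ell^2), tolerance = 1e-12)
    expect_gte(g$Major, g$Minor)
    expect_gt(g$Minor, 0)
    expect_gte(g$AreaHull, g$Area)
  }
})

test_that("rotating a mask by 90 degrees swaps the directional counts", {
  set.seed(8)
  mk <- random_mask(15, 25)
  a <- boundary_counts(mk)
  b <- boundary_counts(t(mk))  # transpose = reflect; swaps x and y roles
  expect_equal(a$Nv, b$Nh)
  expect_equal(a$Nh, b$Nv)
  # elongation direction follows the rotation
  rect <- geometric_features(region_from_mask(matrix(1L, 6, 20)))
  rot <- geometric_features(region_from_mask(matrix(1L, 20, 6)))
  expect_equal(rect$theta, 0)
  expect_equal(rot$theta, 0)  # +-pi/2 folds back into the principal branch
  expect_equal(rect$Major, rot$Major, tolerance = 1e-9)
})

test_that("dilating a disk grows all size features monotonically", {
  radii <- c(4L, 7L, 10L, 13L)
  feats <- lapply(radii, function(r)
    geometric_features(region_from_mask(disk_mask(r))))
  for (f in c("Area", "Dia", "Per", "AreaHull")) {
    v <- vapply(feats, `[[`, numeric(1), f)
    expect_true(all(diff(v) > 0), info = f)
  }
})

test_that("boundary counts match pair enumeration and edge cases", {
  # 1 x 5 horizontal line: 4 horizontal adjacencies, nothing else
  line <- matrix(1L, 1, 5)
  bc <- boundary_counts(line)
  expect_equal(bc$Nh, 4L)
  expect_equal(bc$Nv + bc$Nd1 + bc$Nd2, 0L)
  expect_equal(bc$Per, 4)

  single <- boundary_counts(matrix(1L, 1, 1))
  expect_equal(single$Per, 0)

  set.seed(9)
  shapes <- c(list(matrix(1L, 10, 10), disk_mask(6L)),
              replicate(20, random_mask(12, 12), simplify = FALSE))
  for (mk in shapes) {
    got <- boundary_counts(mk)
    want <- oracle_boundary_counts(mk)
    expect_equal(got$Nv, unname(want["Nv"]))
    expect_equal(got$Nh, unname(want["Nh"]))
    expect_equal(got$Nd1, unname(want["Nd1"]))
    expect_equal(got$Nd2, unname(want["Nd2"]))
    expect_equal(got$Per,
                 unname(want["Nv"] + want["Nh"] +
                        2 * (want["Nd1"] + want["Nd2"])))
  }
  # Euclidean variant weights diagonals by sqrt(2)
  mk <- disk_mask(5L)
  w <- oracle_boundary_counts(mk)
  expect_equal(boundary_counts(mk, diagonal_weight = sqrt(2))$Per,
               unname(w["Nv"] + w["Nh"] + sqrt(2) * (w["Nd1"] + w["Nd2"])))
})

test_that("hull area is convex-consistent", {
  # convex digital disk: hull pixel count stays within digitisation error
  dm <- disk_mask(15L)
  h <- hull_area(dm)
  expect_equal(h$AreaHull, sum(dm), tolerance = 0.03 * sum(dm))
  expect_gte(h$AreaHull, sum(dm))

  # C-shape: hull strictly exceeds the region
  cm <- matrix(0L, 15, 15)
  cm[3:13, 3:5] <- 1L; cm[3:5, 3:13] <- 1L; cm[11:13, 3:13] <- 1L
  expect_gt(hull_area(cm)$AreaHull, sum(cm))

  # four corner pixels of an 11 x 11 square: every lattice point of the
  # square lies in the hull; the polygon itself has shoelace area 100
  corners <- matrix(0L, 11, 11)
  corners[1, 1] <- corners[1, 11] <- corners[11, 1] <- corners[11, 11] <- 1L
  h2 <- hull_area(corners)
  expect_equal(h2$poly_area, 100)
  expect_equal(h2$AreaHull, 121)
  expect_equal(h2$Pn, 40)

  # collinear fallback
  h3 <- hull_area(matrix(1L, 1, 5))
  expect_true(h3$degenerate)
  expect_equal(h3$AreaHull, 5)
})
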