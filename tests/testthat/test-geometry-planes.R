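# Landmark planes, suture-plane construction and its duality with the
# angle measurement.

pracmaCross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

test_that("base plane passes through the three landmarks with cranial normal", {
  pl <- fitBasePlane(c(0, 0, 0), c(-60, -90, 0), c(60, -90, 0))
  expect_equal(pl@normal, c(0, 0, 1))
  expect_lt(abs(signedDistance(pl, rbind(c(0, 0, 0)))), 1e-9)

  # exact interpolation on random non-collinear triples, checked against an
  # independent cross-product construction
  set.seed(42)
  for (i in 1:20) {
    p <- matrix(rnorm(9, sd = 40), 3)
    if (sqrt(sum((pracmaCross(p[2, ] - p[1, ], p[3, ] - p[1, ]))^2)) < 1)
      next
    pl <- fitBasePlane(p[1, ], p[2, ], p[3, ])
    expect_lt(max(abs(signedDistance(pl, p))), 1e-9)
    nOracle <- pracmaCross(p[2, ] - p[1, ], p[3, ] - p[1, ])
    nOracle <- nOracle / sqrt(sum(nOracle^2))
    expect_lt(min(sqrt(sum((pl@normal - nOracle)^2)),
                  sqrt(sum((pl@normal + nOracle)^2))), 1e-9)
  }
})

test_that("collinear or coincident landmarks are rejected", {
  expect_error(fitBasePlane(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               "degenerate")
  expect_error(fitBasePlane(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)),
               "degenerate")
})

test_that("suture plane feet follow the AP-fraction arithmetic", {
  fr <- anatomicalFrame(c(0, 0, 0), c(75, 60, 0), c(75, -60, 0),
                        A = c(0, 0, 0), P = c(150, 0, 0))
  sp <- suturePlanes(fr, 83, 68, abFrac = 0.30, lpFrac = 0.25)
  expect_equal(sp$B, c(45, 0, 0), tolerance = 1e-9)
  expect_equal(sp$L, c(112.5, 0, 0), tolerance = 1e-9)
  # right-angle case: plane perpendicular to AP through the midpoint
  sp90 <- suturePlanes(fr, 90, 68, abFrac = 0.5, lpFrac = 0.25)
  expect_equal(abs(sum(sp90$coronal@normal * c(1, 0, 0))), 1, tolerance = 1e-9)
  expect_equal(sp90$coronal@point, c(75, 0, 0), tolerance = 1e-9)
  # both planes contain their foot and are perpendicular to the midline
  for (p in list(sp$coronal, sp$lambdoid))
    expect_lt(abs(sum(p@normal * fr@midlinePlane@normal)), 1e-9)
})

test_that("suture-plane construction and angle measurement are dual", {
  ph <- headCoarse()
  su <- sutureGeometry() # 83 / 68 / 0.30 / 0.25
  fr <- frameOf(ph, abFrac = su@abFrac, lpFrac = su@lpFrac)
  got <- measureSutureGeometry(fr)
  expect_lt(abs(got@alpha - su@alpha), 0.5)
  expect_lt(abs(got@beta - su@beta), 0.5)
  expect_lt(abs(got@abFrac - su@abFrac), 0.01)
  expect_lt(abs(got@lpFrac - su@lpFrac), 0.01)

  # a second, distinct geometry round-trips too
  su2 <- sutureGeometry(alpha = 95, beta = 75, abFrac = 0.35, lpFrac = 0.2)
  ph2 <- generateHead(phantomSpec(meshResolution = 7, suture = su2))
  fr2 <- frameOf(ph2, abFrac = su2@abFrac, lpFrac = su2@lpFrac)
  got2 <- measureSutureGeometry(fr2)
  expect_lt(abs(got2@alpha - su2@alpha), 0.5)
  expect_lt(abs(got2@beta - su2@beta), 0.5)
})

test_that("misordered suture feet raise a configuration error", {
  fr <- anatomicalFrame(c(0, 0, 0), c(75, 60, 0), c(75, -60, 0),
                        A = c(0, 0, 0), P = c(150, 0, 0))
  expect_error(suturePlanes(fr, 83, 68, abFrac = 0.8, lpFrac = 0.3),
               "configuration")
  expect_error(suturePlanes(fr, 190, 68, abFrac = 0.3, lpFrac = 0.25),
               "0, 180")
})

test_that("plane cutting commutes with rigid transforms", {
  m <- headCoarse()$mesh
  pl <- plane(c(0, 5, 18), c(0.3, -0.1, 1))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(12, -7, 3)
  a <- transformMesh(cutByPlane(m, pl, "positive"), R, tr)
  b <- cutByPlane(transformMesh(m, R, tr), transformPlane(pl, R, tr),
                  "positive")
  expect_equal(nFaces(a), nFaces(b))
  expect_lt(max(abs(vertices(a) - vertices(b))), 1e-6)
})
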