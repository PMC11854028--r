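# Mesh surgery: cutting, offsetting, hole filling, separation, carving.

test_that("plane cut of a sphere yields a hemisphere of the right area", {
  s <- uvSphere(1, nu = 100, nv = 50)
  expect_gt(nFaces(s), 9000)
  up <- cutByPlane(s, plane(c(0, 0, 0), c(0, 0, 1)), "positive")
  expect_equal(meshArea(up), 2 * pi, tolerance = 0.01)
  expect_gte(min(signedDistance(plane(c(0, 0, 0), c(0, 0, 1)),
                                vertices(up))), -1e-6)
  # open boundary lies on the plane
  rim <- unlist(boundaryLoops(up))
  expect_lt(max(abs(vertices(up)[rim, 3])), 1e-6)
})

test_that("cut is a no-op for meshes on the kept side and errors when empty", {
  s <- uvSphere(10, nu = 24, nv = 12)
  same <- cutByPlane(s, plane(c(0, 0, -20), c(0, 0, 1)), "positive")
  expect_identical(nVertices(same), nVertices(s))
  expect_error(cutByPlane(s, plane(c(0, 0, 20), c(0, 0, 1)), "positive"),
               "empty")
})

test_that("cut area matches a quadrature oracle on an ellipsoid cap", {
  ax <- c(60, 40, 50)
  e <- uvSphere(nu = 120, nv = 60, semiAxes = ax)
  cap <- cutByPlane(e, plane(c(0, 0, 10), c(0, 0, 1)), "positive")
  # dense-quadrature oracle on the parametric ellipsoid above z = 10
  nth <- 400; nph <- 800
  eta <- seq(asin(10 / ax[3]), pi / 2, length.out = nth)
  om <- seq(0, 2 * pi, length.out = nph)
  deta <- diff(eta[1:2]); dom <- diff(om[1:2])
  g <- expand.grid(eta = eta[-1] - deta / 2, om = om[-1] - dom / 2)
  # |r_eta x r_om| for r = (a cos e cos w, b cos e sin w, c sin e)
  a <- ax[1]; b <- ax[2]; cc <- ax[3]
  ce <- cos(g$eta); se <- sin(g$eta); co <- cos(g$om); so <- sin(g$om)
  nx <- b * cc * ce^2 * co
  ny <- a * cc * ce^2 * so
  nz <- a * b * ce * se
  oracle <- sum(sqrt(nx^2 + ny^2 + nz^2)) * deta * dom
  expect_equal(meshArea(cap), oracle, tolerance = 0.01)
})

test_that("cutting conserves area between the two sides", {
  m <- headCoarse()$mesh
  pl <- plane(c(3, -4, 22), c(0.2, 0.15, 1))
  up <- cutByPlane(m, pl, "positive")
  dn <- cutByPlane(m, pl, "negative")
  expect_equal(meshArea(up) + meshArea(dn), meshArea(m),
               tolerance = 1e-3)
})

test_that("inward offset of a sphere is a concentric sphere", {
  s <- uvSphere(50, nu = 100, nv = 50)
  off <- offsetInward(s, 2.8)
  r <- sqrt(rowSums(vertices(off)^2))
  expect_lt(max(abs(r - 47.2)), 0.1)
  expect_identical(offsetInward(s, 0), s)
})

test_that("offset distance is recovered by nearest-distance measurement", {
  ph <- headCoarse()
  off <- offsetInward(ph$mesh, 2.8)
  d <- thicknessBetween(off, ph$mesh,
                        plane(c(0, 0, -200), c(0, 0, 1)))@distances
  expect_true(all(abs(d - 2.8) < 0.15))
})

test_that("excessive offset fails loudly", {
  s <- uvSphere(3, nu = 24, nv = 12)
  expect_error(offsetInward(s, 5), "offset-failure")
})

test_that("hole filling restores watertightness and leaves the rim open", {
  s <- uvSphere(30, nu = 40, nv = 20)
  holed <- triSurface(vertices(s), faces(s)[-c(10, 480, 900), , drop = FALSE])
  expect_gt(length(boundaryLoops(holed)), 0)
  closed <- closeHoles(holed)
  expect_identical(boundaryLoops(closed), list())
  expect_identical(closeHoles(s), s) # already closed: unchanged

  # cut phantom with synthetic suture gaps: fill all but the base rim
  cut <- cutByPlane(headCoarse()$mesh, plane(c(0, 0, 0), c(0, 0, 1)),
                    "positive")
  cen <- (vertices(cut)[faces(cut)[, 1], ] + vertices(cut)[faces(cut)[, 2], ] +
            vertices(cut)[faces(cut)[, 3], ]) / 3
  # three well-separated disk-shaped gaps: a face plus its edge neighbours
  seeds <- c(which.max(0.8 * cen[, 3] + cen[, 1]),
             which.max(cen[, 2] + 0.5 * cen[, 3]),
             which.max(-cen[, 2] + 0.5 * cen[, 3]))
  f <- faces(cut)
  gap <- unique(unlist(lapply(seeds, function(si)
    which(rowSums(matrix(f %in% f[si, ], nrow(f))) >= 2))))
  expect_gt(length(gap), 3)
  holey <- triSurface(vertices(cut), faces(cut)[-gap, , drop = FALSE])
  filled <- closeHoles(holey, keepOpen = plane(c(0, 0, 0), c(0, 0, 1)))
  lps <- boundaryLoops(filled)
  expect_length(lps, 1) # only the base rim remains
  # Euler characteristic of a disk: V - E + F = 1
  me <- nrow(unique(rbind(
    t(apply(faces(filled)[, c(1, 2)], 1, sort)),
    t(apply(faces(filled)[, c(2, 3)], 1, sort)),
    t(apply(faces(filled)[, c(3, 1)], 1, sort)))))
  expect_identical(nVertices(filled) - me + nFaces(filled), 1L)
})

test_that("inner and outer skull tables separate cleanly", {
  outer <- uvSphere(50, nu = 60, nv = 30)
  inner <- uvSphere(47.5, nu = 60, nv = 30)
  innerFlip <- triSurface(vertices(inner), faces(inner)[, c(1, 3, 2)])
  shell <- triSurface(rbind(vertices(outer), vertices(innerFlip)),
                      rbind(faces(outer), faces(innerFlip) + nVertices(outer)))
  res <- separateInnerOuter(shell, plane(c(0, 0, 0), c(0, 0, 1)),
                            rimBand = 6)
  rOut <- mean(sqrt(rowSums(vertices(res$outer)^2)))
  rIn <- mean(sqrt(rowSums(vertices(res$inner)^2)))
  expect_equal(rOut, 50, tolerance = 0.01)
  expect_equal(rIn, 47.5, tolerance = 0.01)
  # all retained faces come from the input
  expect_lte(nFaces(res$inner) + nFaces(res$outer), nFaces(shell))
  # the rim band removes the lower caps (everything within rimBand of the
  # plane on these full closed surfaces)
  expect_gt(nFaces(res$inner) + nFaces(res$outer), 0.35 * nFaces(shell))
  # single-surface input cannot be separated
  expect_error(separateInnerOuter(outer, plane(c(0, 0, 0), c(0, 0, 1)),
                                  rimBand = 6), "separation")
})

test_that("osteotomy carving cuts two slots with four notch sets", {
  ph <- headCoarse()
  mod <- modelCoarse()
  pre <- buildSModelNoCarve(ph)
  nPre <- length(boundaryLoops(pre$mesh))
  nPost <- length(boundaryLoops(mod@shell))
  expect_identical(nPost, nPre + 2L) # one new loop per parasagittal slot
  expect_named(mod@notchSets, c("anterior_left", "anterior_right",
                                "posterior_left", "posterior_right"))
  expect_true(all(vapply(mod@notchSets, length, 1L) > 0))
  expect_false(anyDuplicated(unlist(mod@notchSets)) > 0)

  # slot boundary vertices sit on the kerf planes around +/- lateralOffset
  lps <- boundaryLoops(mod@shell)
  hts <- vapply(lps, function(l)
    mean(signedDistance(mod@frame@basePlane,
                        vertices(mod@shell)[l, , drop = FALSE])), 1)
  slots <- lps[order(hts, decreasing = TRUE)[1:2]]
  lat <- abs(vertices(mod@shell)[unlist(slots), ] %*%
               mod@frame@midlinePlane@normal)
  expect_true(all(abs(lat - 25) < 1)) # within 1 mm of the cut line (kerf 1)

  expect_error(osteotomySpec(kerf = 0), "kerf")
  expect_error(osteotomySpec(notchFractions = c(0, 0.5)), "fraction")
})

test_that("carving leaves the mesh outside the cut tubes untouched", {
  ph <- headCoarse()
  pre <- buildSModelNoCarve(ph)
  carved <- carveOsteotomies(pre$mesh, pre$frame, osteotomySpec())$mesh
  lat <- abs(vertices(pre$mesh) %*% pre$frame@midlinePlane@normal)
  edge <- sqrt(mean(faceAreas(pre$mesh)) * 4 / sqrt(3))
  farIdx <- which(abs(lat - 25) > 0.5 + 2 * edge)
  far <- vertices(pre$mesh)[farIdx, , drop = FALSE]
  d <- SpringCranio:::.cppNearestSurfaceDistance(far, vertices(carved),
                                                 faces(carved))
  expect_lt(max(d), 1e-9)
})
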