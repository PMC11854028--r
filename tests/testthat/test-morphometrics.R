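# Thickness maps, AP points, suture angles, population averages, shape
# metrics and rank correlation.

test_that("thickness between concentric spheres equals the gap", {
  a <- uvSphere(50, nu = 80, nv = 40)
  b <- uvSphere(47.5, nu = 80, nv = 40)
  tm <- thicknessBetween(a, b, plane(c(0, 0, 0), c(0, 0, 1)))
  expect_true(all(abs(tm@distances - 2.5) < 0.05))
  expect_equal(tm@mean, 2.5, tolerance = 0.005)
  # identical surfaces: zero distance
  tm0 <- thicknessBetween(a, a, plane(c(0, 0, 0), c(0, 0, 1)))
  expect_lt(max(tm0@distances), 1e-9)
})

test_that("thickness to a translated sphere matches the analytic oracle", {
  a <- uvSphere(50, nu = 60, nv = 30)
  b <- uvSphere(47.5, nu = 120, nv = 60, center = c(1, 0, 0))
  tm <- thicknessBetween(a, b, plane(c(0, 0, 0), c(0, 0, 1)))
  va <- vertices(a)[signedDistance(plane(c(0, 0, 0), c(0, 0, 1)),
                                   vertices(a)) >= 0, ]
  oracle <- sqrt(rowSums(sweep(va, 2, c(1, 0, 0))^2)) - 47.5
  expect_lt(max(abs(tm@distances - oracle)), 0.05)
})

test_that("thickness errors when no vertices lie above the crop plane", {
  a <- uvSphere(10, nu = 24, nv = 12)
  expect_error(thicknessBetween(a, a, plane(c(0, 0, 50), c(0, 0, 1))),
               "empty-measurement")
})

test_that("crop plane sits at the requested height fraction", {
  s <- cutByPlane(uvSphere(100, nu = 60, nv = 30),
                  plane(c(0, 0, 0), c(0, 0, 1)), "positive")
  base <- plane(c(0, 0, 0), c(0, 0, 1))
  cp <- cropPlaneAtFraction(s, base, 0.25)
  expect_equal(sum(cp@point * cp@normal), 25, tolerance = 0.01)
  cp0 <- cropPlaneAtFraction(s, base, 0)
  expect_equal(cp0@point, base@point)
  # tilted mesh: offset equals fraction of the max signed distance (vertex
  # scan oracle)
  m <- headCoarse()$mesh
  tilt <- plane(c(0, 0, 2), c(0.2, 0.1, 1))
  cp2 <- cropPlaneAtFraction(m, tilt, 0.25)
  hmax <- max(signedDistance(tilt, vertices(m)))
  expect_equal(signedDistance(cp2, rbind(tilt@point)), -0.25 * hmax,
               tolerance = 1e-9)
  expect_error(cropPlaneAtFraction(m, plane(c(0, 0, 500), c(0, 0, 1)), 0.25),
               "below")
})

test_that("A and P are the AP extremes of the base-plane section", {
  e <- uvSphere(nu = 80, nv = 40, semiAxes = c(60, 90, 70)) # AP along y
  base <- plane(c(0, 0, 0), c(0, 0, 1))
  ap <- findAPPoints(e, base, anterior = c(0, 90, 0))
  expect_equal(sqrt(sum((ap$A - ap$P)^2)), 180, tolerance = 0.5)
  expect_gt(ap$A[2], 85)
  expect_lt(ap$P[2], -85)
  s <- uvSphere(50, nu = 60, nv = 30)
  aps <- findAPPoints(s, base, anterior = c(0, 60, 0))
  expect_equal(sqrt(sum((aps$A - aps$P)^2)), 100, tolerance = 0.5)
  # exhaustive scan oracle on the phantom section
  ph <- headCoarse()
  app <- findAPPoints(ph$mesh, base, anterior = ph$landmarks$nasion)
  sec <- SpringCranio:::.planeSection(ph$mesh, base)
  proj <- sec[, 2]
  expect_equal(app$A[2], max(proj), tolerance = 1e-6)
  expect_equal(app$P[2], min(proj), tolerance = 1e-6)
})

test_that("suture angles follow the point-angle definition", {
  mkframe <- function(bregma, lambdaPt)
    anatomicalFrame(c(0, 0, 0), c(75, 60, 0), c(75, -60, 0),
                    A = c(0, 0, 0), P = c(150, 0, 0),
                    bregma = bregma, lambdaPt = lambdaPt,
                    abFrac = 0.30, lpFrac = 0.25)
  # bregma straight above B: right angle; above the midpoint with
  # abFrac = 0.5 likewise
  g <- measureSutureGeometry(mkframe(c(45, 0, 100), c(112.5, 0, 90)))
  expect_equal(g@alpha, 90, tolerance = 1e-9)
  expect_equal(g@beta, 90, tolerance = 1e-9)
  expect_equal(g@abFrac, 0.30, tolerance = 1e-12)
  expect_equal(g@lpFrac, 0.25, tolerance = 1e-12)
  # vector-angle oracle: bregma at (35, 0, 100), B at (45, 0, 0):
  # angle(A - B, bregma - B) = acos(450 / (45 * sqrt(10100)))
  g2 <- measureSutureGeometry(mkframe(c(35, 0, 100), c(120, 0, 80)))
  expect_equal(g2@alpha, acos(450 / (45 * sqrt(100^2 + 10^2))) * 180 / pi,
               tolerance = 1e-9)
  expect_equal(g2@beta,
               acos((37.5 * 7.5) / (37.5 * sqrt(7.5^2 + 80^2))) * 180 / pi,
               tolerance = 1e-9)
  # degenerate: bregma on the AP line
  expect_error(measureSutureGeometry(mkframe(c(45, 0, 0), c(120, 0, 80))),
               "degenerate")
})

test_that("population averaging is the arithmetic mean with sds", {
  one <- list(skin = 2.9, skull = 2.4,
              suture = sutureGeometry(80, 70, 0.31, 0.24))
  p1 <- populationAverage(list(one))
  expect_equal(p1@skinThickness, 2.9)
  expect_equal(p1@suture@alpha, 80)
  two <- list(skin = 2.7, skull = 2.6,
              suture = sutureGeometry(86, 66, 0.29, 0.26))
  p2 <- populationAverage(list(one, two))
  expect_equal(p2@suture@alpha, 83)
  expect_equal(p2@skinThickness, 2.8)
  expect_equal(unname(p2@sds["alpha"]), sd(c(80, 86)))
  # k identical copies average to themselves
  pk <- populationAverage(rep(list(one), 5))
  expect_equal(pk@suture@beta, 70)
  expect_error(populationAverage(list()), "empty")
})

test_that("population draws recover their generating means", {
  specs <- generatePopulation(100, seed = 7)
  alphas <- vapply(specs, function(s) s@suture@alpha, 1)
  expect_lt(abs(mean(alphas) - 83), 1)
  skins <- vapply(specs, function(s) s@skinThickness, 1)
  expect_lt(abs(mean(skins) - 2.8), 2 * 0.4 / sqrt(100) * 2 + 0.05)
})

test_that("shape metrics give the constructed extents and CI", {
  e <- uvSphere(nu = 80, nv = 40, semiAxes = c(48, 62.5, 55)) # AP = y
  fr <- anatomicalFrame(c(0, 62.5, 0), c(-48, 0, 0), c(48, 0, 0), mesh = e)
  sm <- shapeMetrics(e, fr)
  expect_equal(sm@ofd, 125, tolerance = 0.5)
  expect_equal(sm@bpd, 96, tolerance = 0.5)
  expect_equal(sm@ci, 0.768, tolerance = 0.005)
  s <- uvSphere(50, nu = 60, nv = 30)
  frs <- anatomicalFrame(c(0, 50, 0), c(-50, 0, 0), c(50, 0, 0), mesh = s)
  expect_equal(shapeMetrics(s, frs)@ci, 1, tolerance = 0.01)
})

test_that("shape metrics are invariant under rigid transforms", {
  ph <- headCoarse()
  fr <- frameOf(ph)
  sm <- shapeMetrics(ph$mesh, fr)
  th <- 0.5
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th))) %*%
    rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  tr <- c(-8, 14, 6)
  mv <- transformMesh(ph$mesh, R, tr)
  lmk <- lapply(ph$landmarks, function(p) drop(R %*% p) + tr)
  fr2 <- anatomicalFrame(lmk$nasion, lmk$tragion_left, lmk$tragion_right,
                         mesh = mv)
  sm2 <- shapeMetrics(mv, fr2)
  expect_equal(sm2@ofd, sm@ofd, tolerance = 1e-3)
  expect_equal(sm2@bpd, sm@bpd, tolerance = 1e-3)
})

test_that("spring opening normalisation is linear in the opening", {
  expect_equal(springOpeningPercent(60), 100)
  expect_equal(springOpeningPercent(0), 0)
  expect_equal(springOpeningPercent(30), 50)
  expect_equal(springOpeningPercent(42), 70)
  expect_error(springOpeningPercent(10, nominal = 0), "config")
})

test_that("Spearman rho matches the direct rank formula and exact p", {
  a <- c(0.71, 0.74, 0.69, 0.77, 0.73, 0.70, 0.75, 0.72)
  b <- c(0.721, 0.718, 0.701, 0.778, 0.729, 0.712, 0.755, 0.716)
  r <- spearmanRho(a, b)
  dd <- rank(a) - rank(b)
  n <- length(a)
  expect_equal(r$rho, 1 - 6 * sum(dd^2) / (n * (n^2 - 1)), tolerance = 1e-12)
  expect_equal(spearmanRho(a, a)$rho, 1)
  expect_equal(spearmanRho(a, -a)$rho, -1)
  # exact permutation oracle at n = 6 (full enumeration of 720 permutations)
  a6 <- a[1:6]; b6 <- b[1:6]
  r6 <- spearmanRho(a6, b6)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) !anyDuplicated(p)), ]
  rhoAll <- apply(perms, 1, function(p) cor(rank(a6), rank(b6)[p]))
  pOracle <- mean(abs(rhoAll) >= abs(r6$rho) - 1e-12)
  expect_equal(r6$p, pOracle, tolerance = 1e-12)
  expect_error(spearmanRho(rep(1, 5), 1:5), "constant")
})
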