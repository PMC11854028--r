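# S-model assembly, CT ingestion, spring attachment.

pracmaCross2 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

test_that("the S model carries five regions, notches and the population thickness", {
  mod <- modelCoarse()
  expect_s4_class(mod, "SkullModel")
  expect_setequal(unique(faceLabels(mod@shell)),
                  c("frontal", "coronal_suture", "parietal",
                    "lambdoid_suture", "occipital"))
  expect_length(mod@notchSets, 4)
  expect_equal(mod@thickness, 2.5)
  expect_identical(mod@provenance, "S")
  # region areas partition the shell area
  ar <- faceAreas(mod@shell)
  expect_equal(sum(tapply(ar, faceLabels(mod@shell), sum)), meshArea(mod@shell),
               tolerance = 1e-9)
})

test_that("zero skin offset reproduces the cut head surface", {
  ph <- headCoarse()
  pop <- populationParams(skinThickness = 1e-12)
  pop@skinThickness <- 0 # zero-offset construction
  mod <- tryCatch(buildSModel(ph$mesh, ph$landmarks, pop),
                  error = function(e) e)
  expect_s4_class(mod, "SkullModel")
  base <- fitBasePlane(ph$landmarks$nasion, ph$landmarks$tragion_left,
                       ph$landmarks$tragion_right)
  cut <- cutByPlane(ph$mesh, base, "positive")
  # shell vertices lie on the cut head surface (splitting aside)
  d <- SpringCranio:::.cppNearestSurfaceDistance(
    vertices(mod@shell), vertices(cut), faces(cut))
  expect_lt(max(d), 1e-6)
})

test_that("the built model is deterministic, bit for bit", {
  ph <- headCoarse()
  m1 <- buildSModel(ph$mesh, ph$landmarks)
  m2 <- buildSModel(ph$mesh, ph$landmarks)
  expect_identical(vertices(m1@shell), vertices(m2@shell))
  expect_identical(faces(m1@shell), faces(m2@shell))
  expect_identical(m1@notchSets, m2@notchSets)
})

test_that("scalp thickness is recovered between head and model shell", {
  ph <- headCoarse()
  mod <- modelCoarse()
  base <- mod@frame@basePlane
  crop <- cropPlaneAtFraction(ph$mesh, base, 0.25)
  tm <- thicknessBetween(mod@shell, ph$mesh, crop)
  expect_lt(abs(tm@mean - 2.8) / 2.8, 0.05)
})

test_that("suture geometry of the built model matches the population input", {
  mod <- modelCoarse()
  # measure from the model's own frame and the carved shell's suture planes
  bandW <- measureSutureBandWidth(mod, "coronal_suture")
  expect_lt(abs(bandW - 2) / 2, 0.2)
  ang <- function(pl, frame) {
    ax <- SpringCranio:::.frameAxes(frame)
    tr <- pracmaCross2(pl@normal, ax$lat) # trace direction in midline plane
    tr <- tr / sqrt(sum(tr^2))
    if (sum(tr * ax$up) < 0) tr <- -tr
    acos(pmin(1, abs(sum(tr * ax$up)))) * 180 / pi
  }
  # coronal plane tilt from vertical equals 90 - alpha
  tilt <- ang(mod@coronalPlane, mod@frame)
  expect_lt(abs(tilt - (90 - 83)), 0.5)
})

test_that("CT ingestion scales uniformly and honours measured landmarks", {
  s <- uvSphere(50, nu = 48, nv = 24)
  ph <- headCoarse()
  mod1 <- ingestCTModel(cutByPlane(ph$mesh, plane(c(0, 0, 0), c(0, 0, 1)),
                                   "positive"),
                        ph$landmarks, scaleFactor = 1)
  expect_identical(mod1@provenance, "CT")
  # pure scaling of a sphere
  ctr <- colMeans(vertices(s))
  v2 <- sweep(sweep(vertices(s), 2, ctr) * 1.1, 2, -ctr)
  expect_equal(max(sqrt(rowSums(sweep(v2, 2, ctr)^2))), 55, tolerance = 1e-6)
  # measured suture planes pass within 1 mm of bregma and lambda
  mod2 <- ingestCTModel(cutByPlane(ph$mesh, plane(c(0, 0, 0), c(0, 0, 1)),
                                   "positive"),
                        ph$landmarks, scaleFactor = 1)
  expect_lt(abs(signedDistance(mod2@coronalPlane,
                               rbind(ph$landmarks$bregma))), 1)
  expect_lt(abs(signedDistance(mod2@lambdoidPlane,
                               rbind(ph$landmarks$lambda))), 1)
  expect_error(ingestCTModel(s, ph$landmarks, scaleFactor = 0), "input")
})

test_that("springs attach across the midline with table stiffnesses", {
  mod <- attachSprings(modelCoarse(), c("S12", "S10"))
  expect_length(mod@springs, 2)
  tab <- defaultSpringTable()
  expect_equal(mod@springs$anterior@stiffness,
               tab$stiffness[tab$model == "S12"])
  expect_equal(mod@springs$posterior@stiffness,
               tab$stiffness[tab$model == "S10"])
  expect_false(mod@springs$anterior@stiffness ==
                 mod@springs$posterior@stiffness)
  symm <- attachSprings(modelCoarse(), c("S12", "S12"))
  expect_equal(symm@springs$anterior@stiffness,
               symm@springs$posterior@stiffness)
  # attachment nodes sit on opposite sides of the midline
  V <- vertices(mod@shell)
  lat <- drop(V %*% mod@frame@midlinePlane@normal)
  for (s in mod@springs)
    expect_lt(lat[s@nodeA] * lat[s@nodeB], 0)
  expect_error(attachSprings(modelCoarse(), c("S99", "S12")), "unknown")
  broken <- modelCoarse()
  broken@notchSets <- list()
  expect_error(attachSprings(broken, c("S12", "S12")), "notch")
})
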