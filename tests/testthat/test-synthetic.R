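# Synthetic phantom generators.

test_that("the default phantom has the constructed extents and CI", {
  ph <- headCoarse()
  fr <- frameOf(ph)
  sm <- shapeMetrics(ph$mesh, fr)
  expect_equal(sm@ci, 0.768, tolerance = 0.005)
  expect_equal(sm@ofd, 125, tolerance = 1)
  expect_equal(sm@bpd, 96, tolerance = 1)
  # base-plane landmarks are on the base plane by construction
  base <- fitBasePlane(ph$landmarks$nasion, ph$landmarks$tragion_left,
                       ph$landmarks$tragion_right)
  expect_lt(abs(signedDistance(base, rbind(ph$landmarks$nasion))), 1e-9)
})

test_that("generated meshes are valid closed outward-oriented surfaces", {
  ph <- headCoarse()
  expect_true(validObject(ph$mesh))
  expect_length(boundaryLoops(ph$mesh), 0)
  expect_gt(signedVolume(ph$mesh), 0)
  expect_error(generateHead(phantomSpec(meshResolution = 60)), "coarse")
})

test_that("the generator is deterministic given a seed", {
  s <- phantomSpec(meshResolution = 8, jitter = 0.2, seed = 11L)
  m1 <- generateHead(s)$mesh
  m2 <- generateHead(s)$mesh
  expect_identical(vertices(m1), vertices(m2))
  m3 <- generateHead(phantomSpec(meshResolution = 8, jitter = 0.2,
                                 seed = 12L))$mesh
  expect_false(identical(vertices(m1), vertices(m3)))
})

test_that("bregma and lambda encode the configured suture geometry", {
  ph <- headCoarse()
  fr <- frameOf(ph, abFrac = 0.30, lpFrac = 0.25)
  g <- measureSutureGeometry(fr)
  expect_lt(abs(g@alpha - 83), 0.5)
  expect_lt(abs(g@beta - 68), 0.5)
})

test_that("two-layer phantoms have the constructed layer thicknesses", {
  tl <- generateTwoLayer(phantomSpec(meshResolution = 6))
  base <- fitBasePlane(tl$landmarks$nasion, tl$landmarks$tragion_left,
                       tl$landmarks$tragion_right)
  crop <- cropPlaneAtFraction(tl$skin, base, 0.25)
  skin <- thicknessBetween(tl$skin, tl$skullOuter, crop)
  skull <- thicknessBetween(tl$skullOuter, tl$skullInner, crop)
  expect_lt(abs(skin@mean - 2.8) / 2.8, 0.05)
  expect_lt(abs(skull@mean - 2.5) / 2.5, 0.05)
  # against the nearest-distance oracle on a random convex-ish spec
  sp <- phantomSpec(ofd = 140, bpd = 110, height = 85, skinThickness = 3.4,
                    skullThickness = 2.1, meshResolution = 7)
  tl2 <- generateTwoLayer(sp)
  b2 <- fitBasePlane(tl2$landmarks$nasion, tl2$landmarks$tragion_left,
                     tl2$landmarks$tragion_right)
  t2 <- thicknessBetween(tl2$skin, tl2$skullOuter,
                         cropPlaneAtFraction(tl2$skin, b2, 0.25))
  expect_lt(abs(t2@mean - 3.4) / 3.4, 0.05)
})

test_that("thickness recovery holds for offsets up to 5 mm", {
  ph <- headCoarse()
  for (d in c(1, 5)) {
    off <- offsetInward(ph$mesh, d)
    tm <- thicknessBetween(ph$mesh, off,
                           plane(c(0, 0, 0), c(0, 0, 1)))
    expect_gt(tm@mean, 0.95 * d)
    expect_lt(tm@mean, 1.05 * d)
  }
})

test_that("population generation is reproducible and respects bounds", {
  p1 <- generatePopulation(8, seed = 3)
  p2 <- generatePopulation(8, seed = 3)
  expect_identical(vapply(p1, function(s) s@ofd, 1),
                   vapply(p2, function(s) s@ofd, 1))
  # degenerate distributions give identical specs
  degen <- lapply(defaultPopulationDistributions(), function(d) c(d[1], 0))
  pd <- generatePopulation(8, degen, seed = 1)
  expect_length(unique(vapply(pd, function(s) s@ofd, 1)), 1)
  expect_true(all(vapply(pd, function(s) s@bpd < s@ofd, TRUE)))
  expect_error(generatePopulation(0), "n must be")
  expect_error(generatePopulation(3, list(alpha = c(83, -1))), "invalid")
})

test_that("the full pipeline runs end to end on a coarse phantom", {
  ph <- generateHead(phantomSpec(meshResolution = 7.5))
  mod <- attachSprings(buildSModel(ph$mesh, ph$landmarks), c("S12", "S12"))
  sys <- femAssemble(mod)
  sol <- solveQuasistatic(sys, mod@springs,
                          femSchedule(nRamp = 3, nLog = 8))
  rep <- extractOutputs(sol, mod@frame)
  ci <- setNames(rep$metrics$ci, rep$metrics$timepoint)
  expect_gt(ci["FU"], ci["PREOP"])
  expect_true(all(diff(sol@openings[, 1]) > -1e-6))
})
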