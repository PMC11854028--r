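# Shell finite-element core: plate benchmark, spring law, equilibrium
# oracle, viscoelastic limits, conservation properties.

linearPlateSolve <- function(E, nu = 0.3, nx = 28, ny = 32, P = 1e-3) {
  mesh <- equiPlate(nx, ny, 100 / nx)
  bnd <- unique(unlist(boundaryLoops(mesh)))
  sys <- femSystem(mesh, bnd, list(m = material(E, nu)), 1L, thickness = 1)
  res <- SpringCranio:::.cppShellAssemble(
    sys@X0, sys@X0, sys@faces, sys@faceMu, sys@faceLam, sys@thickness,
    sys@hinges, sys@hingeK, sys@hingeTheta0, sys@faceGroup, sys@hingeGroup,
    1L, 1.0, TRUE)
  V <- vertices(mesh)
  ctr <- which.min((V[, 1] - 50)^2 + (V[, 2] - mean(V[, 2]))^2)
  free <- rep(!sys@fixed, each = 3)
  f <- numeric(3 * nrow(sys@X0))
  f[3 * (ctr - 1) + 3] <- P
  u <- Matrix::solve(res$K[free, free], f[free])
  list(w = u[which(which(free) == 3 * (ctr - 1) + 3)],
       nel = nFaces(mesh))
}

test_that("clamped plate under a centre point load matches Kirchhoff theory", {
  E <- 1000; nu <- 0.3; P <- 1e-3
  r <- linearPlateSolve(E, nu, P = P)
  expect_gt(r$nel, 1500)
  D <- E * 1^3 / (12 * (1 - nu^2))
  wK <- 0.00560 * P * 100^2 / D # series solution, clamped square plate
  expect_lt(abs(r$w - wK) / wK, 0.05)
})

test_that("displacements scale inversely with the modulus in the linear regime", {
  r1 <- linearPlateSolve(1000, nx = 14, ny = 16)
  r2 <- linearPlateSolve(2000, nx = 14, ny = 16)
  expect_equal(r1$w / r2$w, 2, tolerance = 1e-9)
})

test_that("a system without constraints is rejected", {
  mesh <- equiPlate(6, 6, 10)
  expect_error(femSystem(mesh, integer(0), list(m = material(100, 0.3))),
               "constraint")
})

test_that("spring force is linear, push-only and zero at the nominal length", {
  s <- springElement("S12", 0.52, 60)
  expect_identical(springForce(s, 60), 0)
  expect_identical(springForce(s, 70), 0) # never pulls
  expect_equal(springForce(s, 30) / springForce(s, 45), 2)
  expect_error(springForce(s, -1), ">= 0")
  expect_error(springElement("S12", -1), "stiffness")
})

test_that("no springs means no displacement at any time", {
  toy <- flapToy(material(500, 0.3))
  sol <- solveQuasistatic(toy$sys, list(),
                          femSchedule(tPostop = 1, tEnd = 5, nRamp = 2,
                                      nLog = 2))
  expect_lt(max(abs(sol@displacements$POSTOP)), 1e-12)
  expect_lt(max(abs(sol@displacements$FU)), 1e-12)
})

test_that("two-flap equilibrium matches the 1-dof energy-minimisation oracle", {
  toy <- flapToy(material(2e5, 0.3)) # near-rigid flaps
  spr <- springElement("S12", 0.52, 60, toy$a, toy$bNode)
  sol <- elasticSolve(toy$sys, list(spr))
  opFEM <- sol@openings[nrow(sol@openings), 1]
  Ktot <- toyHingeStiffness(toy$sys)
  en <- function(phi) {
    d <- 2 * (toy$b + toy$Hf * sin(phi))
    Ktot * phi^2 + ifelse(d < 60, 0.5 * 0.52 * (60 - d)^2, 0)
  }
  phiStar <- optimize(en, c(0, pi / 3), tol = 1e-12)$minimum
  opOracle <- 2 * (toy$b + toy$Hf * sin(phiStar))
  expect_lt(abs(opFEM - opOracle) / opOracle, 0.01)
})

test_that("reactions balance the applied spring forces to 1e-6 relative", {
  toy <- flapToy(material(800, 0.35))
  spr <- springElement("S12", 0.52, 60, toy$a, toy$bNode)
  sol <- elasticSolve(toy$sys, list(spr))
  expect_lt(max(sol@diagnostics$balance, na.rm = TRUE), 1e-6)
  expect_lt(max(sol@diagnostics$residual, na.rm = TRUE), 1e-6)
})

test_that("spring work equals stored strain energy in the elastic case", {
  toy <- flapToy(material(800, 0.35))
  spr <- springElement("S12", 0.52, 60, toy$a, toy$bNode)
  sol <- solveQuasistatic(toy$sys, list(spr),
                          femSchedule(tPostop = 1, tEnd = 2, nRamp = 20,
                                      nLog = 1))
  W <- sol@diagnostics$springWork
  Es <- sol@diagnostics$strainEnergy[length(sol@diagnostics$strainEnergy)]
  expect_lt(abs(W - Es) / Es, 0.01)
})

test_that("the instantaneous viscoelastic response equals the elastic one", {
  matE <- material(2000, 0.3)
  matV <- material(2000, 0.3, pronyG = 0.5, pronyTau = 1e4)
  toyE <- flapToy(matE); toyV <- flapToy(matV)
  sprE <- springElement("S12", 0.52, 60, toyE$a, toyE$bNode)
  sprV <- springElement("S12", 0.52, 60, toyV$a, toyV$bNode)
  solE <- elasticSolve(toyE$sys, list(sprE))
  solV <- elasticSolve(toyV$sys, list(sprV))
  i1E <- which(abs(solE@timePoints - 1) < 1e-9)
  i1V <- which(abs(solV@timePoints - 1) < 1e-9)
  expect_equal(solV@openings[i1V, 1], solE@openings[i1E, 1],
               tolerance = 1e-3)
})

test_that("the long-time viscoelastic opening approaches the relaxed-modulus solution", {
  g1 <- 0.5; E0 <- 2000
  matV <- material(E0, 0.3, pronyG = g1, pronyTau = 100)
  toyV <- flapToy(matV)
  sprV <- springElement("S12", 0.52, 60, toyV$a, toyV$bNode)
  solV <- solveQuasistatic(toyV$sys, list(sprV),
                           femSchedule(tPostop = 1, tEnd = 5000, nRamp = 4,
                                       nLog = 25))
  opV <- solV@openings[nrow(solV@openings), 1]
  toyR <- flapToy(material(E0 * (1 - g1), 0.3))
  sprR <- springElement("S12", 0.52, 60, toyR$a, toyR$bNode)
  solR <- elasticSolve(toyR$sys, list(sprR))
  opR <- solR@openings[nrow(solR@openings), 1]
  expect_lt(abs(opV - opR) / opR, 0.02)
  # creep is monotone
  expect_true(all(diff(solV@openings[, 1]) > -1e-6))
})

test_that("final opening is non-decreasing in spring stiffness (S10 < S12 < S14)", {
  tab <- defaultSpringTable()
  ops <- vapply(tab$stiffness, function(k) {
    toy <- flapToy(material(2000, 0.3))
    spr <- springElement("X", k, 60, toy$a, toy$bNode)
    sol <- elasticSolve(toy$sys, list(spr))
    sol@openings[nrow(sol@openings), 1]
  }, 1)
  expect_true(all(diff(ops) > 0))
})

test_that("openings are mesh-refinement consistent on the phantom", {
  op <- function(res) {
    ph <- generateHead(phantomSpec(meshResolution = res))
    mod <- attachSprings(buildSModel(ph$mesh, ph$landmarks), c("S12", "S12"))
    matE <- lapply(defaultMaterials(), function(m) {
      m@pronyG <- numeric(0); m@pronyTau <- numeric(0); m
    })
    sys <- femAssemble(mod, matE)
    sol <- elasticSolve(sys, mod@springs)
    sol@openings[nrow(sol@openings), ]
  }
  o1 <- op(8)    # ~1.2k elements
  o2 <- op(5.6)  # ~2x elements
  expect_lt(max(abs(o2 - o1) / o1), 0.02)
})

test_that("solution report extracts openings, percentages and shape metrics", {
  toy <- flapToy(material(2000, 0.3))
  spr <- springElement("S12", 0.52, 60, toy$a, toy$bNode)
  sched <- femSchedule(tPostop = 1, tEnd = 432000, nRamp = 3, nLog = 6)
  sol <- solveQuasistatic(toy$sys, list(spr), sched)
  fr <- anatomicalFrame(c(0, 25, 0), c(-20, -15, 0), c(20, -15, 0),
                        A = c(0, 20, 0), P = c(0, -20, 0))
  rep <- extractOutputs(sol, fr)
  expect_setequal(rep$metrics$timepoint, c("PREOP", "POSTOP", "FU"))
  expect_equal(rep$openings$POSTOP_pct,
               100 * rep$openings$POSTOP_mm / 60, tolerance = 1e-12)
  # missing timepoint errors
  short <- solveQuasistatic(toy$sys, list(spr),
                            femSchedule(tPostop = 1, tEnd = 10, nRamp = 2,
                                        nLog = 2))
  expect_error(extractOutputs(short, fr), "missing timepoint")
})
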