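# Shared fixtures and oracle builders. Fixtures are generated in code and
# memoised per test run.

.fixtures <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) assign(name, force(expr), envir = .fixtures)
  .fixtures[[name]]
}

# UV sphere / ellipsoid mesh (closed, outward-oriented)
uvSphere <- function(r = 50, nu = 48, nv = 24, center = c(0, 0, 0),
                     semiAxes = c(r, r, r)) {
  eta <- seq(-pi / 2, pi / 2, length.out = nv + 2)[2:(nv + 1)]
  om <- seq(0, 2 * pi, length.out = nu + 1)[seq_len(nu)]
  V <- cbind(semiAxes[1] * as.vector(outer(cos(om), cos(eta))),
             semiAxes[2] * as.vector(outer(sin(om), cos(eta))),
             rep(semiAxes[3] * sin(eta), each = nu))
  id <- function(i, j) (j - 1L) * nu + ((i - 1L) %% nu) + 1L
  Fl <- list()
  for (j in seq_len(nv - 1)) {
    i <- seq_len(nu)
    Fl[[j]] <- rbind(cbind(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                     cbind(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  bot <- nu * nv + 1L; top <- nu * nv + 2L
  V <- rbind(V, c(0, 0, -semiAxes[3]), c(0, 0, semiAxes[3]))
  i <- seq_len(nu)
  Fl[[nv]] <- cbind(id(i + 1, 1), id(i, 1), bot)
  Fl[[nv + 1]] <- cbind(id(i, nv), id(i + 1, nv), top)
  V <- sweep(V, 2, -center)
  ensureOutward(triSurface(V, do.call(rbind, Fl)))
}

# near-equilateral flat plate mesh in the z = 0 plane
equiPlate <- function(nx, ny, dx) {
  dy <- dx * sqrt(3) / 2
  V <- do.call(rbind, lapply(0:ny, function(j)
    cbind((0:nx) * dx + (j %% 2) * dx / 2, j * dy, 0)))
  id <- function(i, j) j * (nx + 1) + i
  F <- matrix(0L, 0, 3)
  for (j in 0:(ny - 1)) for (i in 1:nx) {
    b0 <- id(i, j); b1 <- id(i + 1, j); a0 <- id(i, j + 1); a1 <- id(i + 1, j + 1)
    if (j %% 2 == 0) F <- rbind(F, c(b0, b1, a0), c(b1, a1, a0))
    else F <- rbind(F, c(b0, b1, a1), c(b0, a1, a0))
  }
  triSurface(V, F)
}

# two vertical rectangular flaps clamped (hinged) at their base lines at
# x = +/- b, with a spring between the top-centre nodes: the 1-dof oracle
# problem for the shell solver
flapToy <- function(mat, b = 15, W = 40, Hf = 50, nx = 6, nz = 8,
                    thickness = 2) {
  flap <- function(side) {
    ys <- seq(-W / 2, W / 2, length.out = nx + 1)
    zs <- seq(0, Hf, length.out = nz + 1)
    V <- cbind(side * b, as.matrix(expand.grid(y = ys, z = zs)))
    id <- function(i, j) (j - 1) * (nx + 1) + i
    F <- matrix(0L, 0, 3)
    for (j in 1:nz) for (i in 1:nx)
      F <- rbind(F, c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                 c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
    triSurface(V, F)
  }
  m1 <- flap(1); m2 <- flap(-1)
  mesh <- triSurface(rbind(vertices(m1), vertices(m2)),
                     rbind(faces(m1), faces(m2) + nVertices(m1)))
  V <- vertices(mesh)
  sys <- femSystem(mesh, which(abs(V[, 3]) < 1e-9), list(m = mat), 1L,
                   thickness = thickness)
  list(sys = sys, b = b, Hf = Hf,
       a = which(abs(V[, 1] - b) < 1e-9 & abs(V[, 2]) < 1e-9 &
                   abs(V[, 3] - Hf) < 1e-9),
       bNode = which(abs(V[, 1] + b) < 1e-9 & abs(V[, 2]) < 1e-9 &
                       abs(V[, 3] - Hf) < 1e-9))
}

# torsional stiffness of the toy's clamped (ghost) hinges along z = 0
toyHingeStiffness <- function(sys) {
  ghost <- sys@hinges[, 4] > sys@nReal
  bottom <- ghost & apply(sys@hinges, 1, function(h)
    all(abs(sys@X0[h[2:3], 3]) < 1e-9))
  sum(sys@hingeK[bottom])
}

headCoarse <- function() fixture("headCoarse",
  generateHead(phantomSpec(meshResolution = 6)))

modelCoarse <- function() fixture("modelCoarse",
  buildSModel(headCoarse()$mesh, headCoarse()$landmarks))

# the build pipeline up to (but excluding) the osteotomy carve, on the
# default coarse phantom
buildSModelNoCarve <- function(ph, pop = populationParams()) {
  fixture("noCarve", {
    basePlane <- fitBasePlane(ph$landmarks$nasion, ph$landmarks$tragion_left,
                              ph$landmarks$tragion_right)
    cut <- cutByPlane(ph$mesh, basePlane, "positive")
    skull <- offsetInward(cut, pop@skinThickness)
    frame <- anatomicalFrame(ph$landmarks$nasion, ph$landmarks$tragion_left,
                             ph$landmarks$tragion_right, mesh = skull,
                             abFrac = pop@suture@abFrac,
                             lpFrac = pop@suture@lpFrac)
    sp <- suturePlanes(frame, pop@suture@alpha, pop@suture@beta)
    labeled <- SpringCranio:::.labelRegions(skull, sp$coronal, sp$lambdoid,
                                            pop@sutureWidth)
    list(mesh = labeled, frame = frame)
  })
}

frameOf <- function(ph, abFrac = NULL, lpFrac = NULL) {
  anatomicalFrame(ph$landmarks$nasion, ph$landmarks$tragion_left,
                  ph$landmarks$tragion_right, mesh = ph$mesh,
                  bregma = ph$landmarks$bregma,
                  lambdaPt = ph$landmarks$lambda,
                  abFrac = abFrac, lpFrac = lpFrac)
}

# elastic static solve shortcut (no creep portion)
elasticSolve <- function(sys, springs) {
  solveQuasistatic(sys, springs,
                   femSchedule(tPostop = 1, tEnd = 2, nRamp = 4, nLog = 1))
}
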