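# Quasi-static, geometrically nonlinear viscoelastic shell FEM.
#
# Element technology: 3-dof/node flat triangles carrying a St. Venant-
# Kirchhoff plane-stress membrane plus hinge-based bending on every interior
# edge (discrete-shells flexural energy). Clamped boundary edges get "ghost"
# hinges - the rest-state mirror of the adjacent triangle, held fixed - so a
# clamped rim resists rotation as well as translation. Large rotations are
# handled naturally: both energies are functions of the current geometry
# only. Viscoelasticity is a Prony relaxation series applied to the elastic
# internal force of each material group (quasi-linear hereditary integral,
# exact exponential recurrence for piecewise-linear force histories).

# Bending calibration: hinge stiffness k_e = D/(2 c) * 3|e|^2 / (2 (A1+A2)),
# with D = E h^3 / (12 (1 - nu^2)). The constant c makes the discrete energy
# reproduce the continuum bending energy of a cylindrically bent plate on
# near-equilateral meshes (measured ratio 1.43, direction spread < 2%).
.BEND_CAL <- 1.43

.planeStress <- function(mat) {
  E <- mat@youngsModulus; nu <- mat@poisson
  list(mu = E / (2 * (1 + nu)), lam = E * nu / (1 - nu^2),
       D = E / (12 * (1 - nu^2)))
}

#' Default shell materials
#'
#' Placeholder elastic/viscoelastic properties for infant calvarial bone and
#' patent sutures: bone E = 421 MPa class, sutures two orders of magnitude
#' softer and nearly incompressible, both with a single-term Prony series
#' (g1 = 0.5, tau1 = 3e4 s) so that half the stiffness relaxes with a time
#' constant of ~8 hours. These are configuration defaults that users should
#' replace with calibrated values; only their orders of magnitude are
#' anatomically motivated.
#'
#' @return named list of [Material-class]: `skull`, `suture`.
#' @export
defaultMaterials <- function() {
  list(skull = material(421, 0.22, pronyG = 0.5, pronyTau = 3e4),
       suture = material(8, 0.45, pronyG = 0.5, pronyTau = 3e4))
}

#' Build a finite-element system from a raw mesh
#'
#' Lower-level companion of [femAssemble()], used directly for benchmark
#' problems (plates, flaps). Ghost hinges are created for every boundary
#' edge whose two endpoints are both fixed.
#'
#' @param mesh a [TriSurface-class].
#' @param fixedVerts integer indices or logical mask of clamped vertices.
#' @param materials list of [Material-class], one per group.
#' @param faceGroup integer vector (per face) into `materials`, or a single
#'   value.
#' @param thickness shell thickness, mm.
#' @return an [FESystem-class].
#' @export
femSystem <- function(mesh, fixedVerts, materials, faceGroup = 1L,
                      thickness = 2.5) {
  n <- nVertices(mesh)
  f <- mesh@faces
  m <- nrow(f)
  if (length(faceGroup) == 1) faceGroup <- rep(as.integer(faceGroup), m)
  fixed <- logical(n)
  fixed[fixedVerts] <- TRUE
  if (!any(fixed))
    stop("constraint error: no constrained vertices (free rigid-body modes)")
  ps <- lapply(materials, .planeStress)
  faceMu <- vapply(ps, `[[`, 1, "mu")[faceGroup]
  faceLam <- vapply(ps, `[[`, 1, "lam")[faceGroup]
  faceD <- (vapply(ps, `[[`, 1, "D")[faceGroup]) * thickness^3
  areas <- faceAreas(mesh)

  me <- .meshEdges(mesh)
  he <- me$he; grp <- me$grp
  firsts <- c(1L, which(diff(grp) != 0) + 1L)
  V <- mesh@vertices
  hing <- list(); hk <- numeric(0); hgrp <- integer(0)
  ghosts <- list()
  for (p in seq_along(me$cnt)) {
    i <- firsts[p]
    if (me$cnt[p] == 2) {
      h1 <- he[i, ]; h2 <- he[i + 1, ]
      le2 <- sum((V[h1[2], ] - V[h1[1], ])^2)
      A12 <- areas[h1[4]] + areas[h2[4]]
      D12 <- (faceD[h1[4]] + faceD[h2[4]]) / 2
      hing[[length(hing) + 1]] <- c(h1[3], h1[1], h1[2], h2[3])
      hk <- c(hk, D12 / (2 * .BEND_CAL) * 3 * le2 / (2 * A12))
      hgrp <- c(hgrp, faceGroup[h1[4]])
    } else {
      h1 <- he[i, ]
      if (fixed[h1[1]] && fixed[h1[2]]) {
        # ghost hinge: mirror the opposite vertex across the edge line
        v1 <- V[h1[1], ]; v2 <- V[h1[2], ]; p0 <- V[h1[3], ]
        t <- .unit(v2 - v1)
        d <- p0 - v1
        gv <- v1 + 2 * sum(d * t) * t - d
        ghosts[[length(ghosts) + 1]] <- gv
        gid <- n + length(ghosts)
        le2 <- sum((v2 - v1)^2)
        hing[[length(hing) + 1]] <- c(h1[3], h1[1], h1[2], gid)
        hk <- c(hk, faceD[h1[4]] / (2 * .BEND_CAL) * 3 * le2 /
                  (2 * 2 * areas[h1[4]]))
        hgrp <- c(hgrp, faceGroup[h1[4]])
      }
    }
  }
  X0 <- rbind(V, do.call(rbind, ghosts))
  H <- do.call(rbind, hing)
  storage.mode(H) <- "integer"
  fixedAll <- c(fixed, rep(TRUE, length(ghosts)))
  th0 <- as.numeric(.cppDihedralAngles(X0, H))
  new("FESystem", X0 = X0, nReal = as.integer(n), faces = f,
      thickness = thickness, fixed = fixedAll,
      faceGroup = as.integer(faceGroup),
      groups = if (!is.null(names(materials))) names(materials)
               else as.character(seq_along(materials)),
      materials = materials, faceMu = faceMu, faceLam = faceLam,
      hinges = H, hingeK = hk, hingeTheta0 = th0,
      hingeGroup = as.integer(hgrp))
}

#' Assemble a SkullModel into a finite-element system
#'
#' Shell elements take the model's homogeneous thickness; the frontal,
#' parietal and occipital regions share the skull material, both suture
#' bands share the suture material. The base rim (the open boundary loop
#' lowest above the base plane) is fully constrained to mimic the tethering
#' of the skull base.
#'
#' @param model a [SkullModel-class].
#' @param materials named list with `skull` and `suture`
#'   [Material-class] entries.
#' @return an [FESystem-class].
#' @export
femAssemble <- function(model, materials = defaultMaterials()) {
  shell <- model@shell
  if (!length(shell@faceLabels)) stop("assembly error: unlabeled faces")
  grpName <- ifelse(grepl("suture", shell@faceLabels), "suture", "skull")
  if (!all(c("skull", "suture") %in% names(materials)))
    stop("assembly error: materials must include 'skull' and 'suture'")
  mats <- materials[c("skull", "suture")]
  faceGroup <- match(grpName, names(mats))
  loops <- boundaryLoops(shell)
  if (!length(loops)) stop("constraint error: shell has no base rim")
  mh <- vapply(loops, function(l)
    mean(signedDistance(model@frame@basePlane,
                        shell@vertices[l, , drop = FALSE])), 1)
  rim <- loops[[which.min(mh)]]
  sys <- femSystem(shell, rim, mats, faceGroup, model@thickness)
  attr(sys, "faceLabels") <- shell@faceLabels
  sys
}

#' Push-only linear spring force
#'
#' `force = stiffness * (freeLength - opening)`, clamped at zero: the
#' distractor pushes its footplates apart but cannot pull them together.
#'
#' @param spring a [SpringElement-class].
#' @param opening current opening, mm (>= 0).
#' @return force in N.
#' @examples
#' s <- springElement("S12", 0.5)
#' springForce(s, 30) # 15 N
#' springForce(s, 70) # 0 N
#' @export
springForce <- function(spring, opening) {
  if (any(opening < 0)) stop("opening must be >= 0")
  pmax(0, spring@stiffness * (spring@freeLength - opening))
}

#' Simulation time grid
#'
#' A short force ramp up to the immediate post-operative snapshot at
#' t = 1 s, then logarithmically spaced points to 5 days (432000 s): creep
#' dynamics span five orders of magnitude in time.
#'
#' @param tPostop time of the POSTOP snapshot (s).
#' @param tEnd end time (s); default 5 days.
#' @param nRamp ramp steps in (0, tPostop].
#' @param nLog log-spaced points in (tPostop, tEnd].
#' @return numeric vector of times including `tPostop` and `tEnd`; the ramp
#'   time is carried as attribute `tRamp`.
#' @export
femSchedule <- function(tPostop = 1, tEnd = 432000, nRamp = 5, nLog = 40) {
  ts <- c(tPostop * seq_len(nRamp) / nRamp,
          exp(seq(log(tPostop), log(tEnd), length.out = nLog + 1))[-1])
  attr(ts, "tRamp") <- tPostop
  ts
}

# spring gradient (of energy) and Hessian triplets at current coordinates
.springTerms <- function(springs, X, scale, nDof) {
  G <- numeric(nDof)
  ti <- tj <- tx <- numeric(0)
  forces <- numeric(length(springs))
  for (si in seq_along(springs)) {
    s <- springs[[si]]
    a <- s@nodeA; b <- s@nodeB
    xa <- X[a, ]; xb <- X[b, ]
    dv <- xa - xb
    d <- sqrt(sum(dv^2))
    if (d >= s@freeLength || d < 1e-9) next
    t <- dv / d
    fmag <- s@stiffness * (s@freeLength - d)
    forces[si] <- fmag * scale
    ia <- 3 * (a - 1) + 1:3; ib <- 3 * (b - 1) + 1:3
    G[ia] <- G[ia] - scale * fmag * t
    G[ib] <- G[ib] + scale * fmag * t
    Hb <- scale * (s@stiffness * outer(t, t) -
                     fmag / d * (diag(3) - outer(t, t)))
    idx <- c(ia, ib)
    blk <- rbind(cbind(Hb, -Hb), cbind(-Hb, Hb))
    ti <- c(ti, rep(idx, times = 6))
    tj <- c(tj, rep(idx, each = 6))
    tx <- c(tx, as.vector(blk))
  }
  list(G = G, ti = ti, tj = tj, tx = tx, forces = forces)
}

.openings <- function(springs, X) vapply(springs, function(s)
  sqrt(sum((X[s@nodeA, ] - X[s@nodeB, ])^2)), 1)

# viscoelastic increment factor per group for step length dt
.viscoFactors <- function(materials, dt) {
  vapply(materials, function(m) {
    if (!length(m@pronyG)) return(1)
     1 - sum(m@pronyG) + sum(m@pronyG * (m@pronyTau / dt) *
                              (1 - exp(-dt / m@pronyTau)))
  }, 1)
}

#' Solve the quasi-static spring expansion
#'
#' At every time-grid point, Newton iteration drives the residual of
#' internal shell forces against spring forces below
#' `tol x (spring force scale)`. The spring load is ramped linearly over
#' the first second (the POSTOP snapshot therefore carries the full load),
#' and the Prony internal variables are updated with the exact exponential
#' recurrence between grid points. Openings are recorded at every time.
#'
#' @param system an [FESystem-class].
#' @param springs list of [SpringElement-class] with attachment nodes set.
#' @param schedule time grid from [femSchedule()].
#' @param control list: `tol` (relative residual, default 1e-6), `maxIter`
#'   (Newton iterations per step, default 40), `verbose`.
#' @return an [ExpansionSolution-class].
#' @export
solveQuasistatic <- function(system, springs, schedule = femSchedule(),
                             control = list()) {
  ctl <- modifyList(list(tol = 1e-6, maxIter = 25, maxStep = 10,
                         verbose = FALSE), control)
  if (!any(system@fixed))
    stop("constraint error: no constrained vertices")
  tRamp <- attr(schedule, "tRamp")
  if (is.null(tRamp)) tRamp <- 1
  n <- nrow(system@X0)
  nDof <- 3 * n
  freeDof <- rep(!system@fixed, each = 3)
  nG <- length(system@materials)
  gSum <- vapply(system@materials, function(m) sum(m@pronyG), 1)

  asm <- function(Uv, cg, hess) {
    X <- system@X0 + matrix(Uv, ncol = 3, byrow = TRUE)
    res <- .cppShellAssemble(X, system@X0, system@faces, system@faceMu,
                             system@faceLam, system@thickness, system@hinges,
                             system@hingeK, system@hingeTheta0,
                             system@faceGroup, system@hingeGroup, nG, cg,
                             hess)
    res$X <- X
    res
  }

  # mutable solver state
  U <- numeric(nDof)
  Gel <- matrix(0, nDof, nG) # committed elastic gradient per group
  rState <- lapply(seq_len(nG), function(g)
    lapply(system@materials[[g]]@pronyG, function(gg) numeric(nDof)))
  Fprev <- numeric(nDof)
  Uprev <- numeric(nDof)
  tPrev <- 0
  lastRes <- NULL # converged assembly results at tPrev

  # storage over the schedule
  tps <- c(0, as.numeric(schedule))
  nt <- length(tps)
  openings <- matrix(NA_real_, nt, length(springs))
  openings[1, ] <- .openings(springs, system@X0)
  diag_ <- list(residual = numeric(nt), balance = numeric(nt),
                springWork = 0, strainEnergy = numeric(nt),
                iterations = integer(nt))
  snapshots <- list(PREOP = matrix(0, system@nReal, 3))

  # attempt one implicit step tPrev -> tk; returns the converged pieces or
  # NULL on Newton failure (caller then bisects the step)
  tryStep <- function(tk) {
    dt <- tk - tPrev
    s <- min(1, tk / tRamp)
    cg <- .viscoFactors(system@materials, dt)
    eFac <- lapply(seq_len(nG), function(g) {
      m <- system@materials[[g]]
      lapply(seq_along(m@pronyG), function(i)
        c(e = exp(-dt / m@pronyTau[i]),
          w = (m@pronyTau[i] / dt) * (1 - exp(-dt / m@pronyTau[i]))))
    })
    # total viscoelastic force F = (1 - sum g_i) f + sum_i g_i r_i, with
    # r_i the exponentially-faded force history (exact for piecewise-linear
    # f); dF/df equals the .viscoFactors increment factor used as tangent
    # scaling
    viscousGrad <- function(Gnew) {
      Gv <- numeric(nDof)
      for (g in seq_len(nG)) {
        m <- system@materials[[g]]
        acc <- (1 - gSum[g]) * Gnew[, g]
        for (i in seq_along(m@pronyG)) {
          ri <- eFac[[g]][[i]]["e"] * rState[[g]][[i]] +
            eFac[[g]][[i]]["w"] * (Gnew[, g] - Gel[, g])
          acc <- acc + m@pronyG[i] * ri
        }
        Gv <- Gv + acc
      }
      Gv
    }
    residualAt <- function(Uv, hess = FALSE) {
      res <- asm(Uv, cg, hess)
      st <- .springTerms(springs, res$X, s, nDof)
      list(res = res, st = st, R = viscousGrad(res$grad) + st$G,
           fscale = max(1, sum(abs(st$forces))))
    }
    Utry <- U
    ra <- residualAt(Utry, hess = TRUE)
    for (it in 0:ctl$maxIter) {
      rnorm2 <- sqrt(sum(ra$R[freeDof]^2))
      if (rnorm2 <= ctl$tol * ra$fscale)
        return(list(U = Utry, ra = ra, eFac = eFac, it = it, s = s))
      if (it == ctl$maxIter) return(NULL)
      K <- ra$res$K
      if (length(ra$st$ti))
        K <- K + sparseMatrix(i = ra$st$ti, j = ra$st$tj, x = ra$st$tx,
                              dims = c(nDof, nDof))
      Kff <- forceSymmetric(K[freeDof, freeDof])
      du <- NULL
      shift <- 0
      for (tryI in 1:6) {
        ch <- tryCatch(Cholesky(if (shift > 0)
          Kff + shift * Diagonal(nrow(Kff)) else Kff, LDL = FALSE),
          error = function(e) NULL)
        if (!is.null(ch)) {
          du <- as.numeric(solve(ch, -ra$R[freeDof]))
          break
        }
        shift <- if (shift == 0) 1e-6 * mean(abs(diag(Kff))) else shift * 100
      }
      if (is.null(du)) return(NULL)
      # cap the increment (large first steps from flat states overshoot)
      mx <- max(abs(du))
      if (mx > ctl$maxStep) du <- du * (ctl$maxStep / mx)
      alpha <- 1
      improved <- FALSE
      while (alpha >= 1e-4) {
        Unew <- Utry
        Unew[freeDof] <- Utry[freeDof] + alpha * du
        raNew <- residualAt(Unew, hess = TRUE)
        if (sqrt(sum(raNew$R[freeDof]^2)) < rnorm2) {
          Utry <- Unew
          ra <- raNew
          improved <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (!improved) return(NULL)
    }
    NULL
  }

  commit <- function(stepRes, tk) {
    Xc <- stepRes$ra$res$X
    ar <- 0.5 * sqrt(rowSums(.rowCross(
      Xc[system@faces[, 2], , drop = FALSE] -
        Xc[system@faces[, 1], , drop = FALSE],
      Xc[system@faces[, 3], , drop = FALSE] -
        Xc[system@faces[, 1], , drop = FALSE])^2))
    if (any(ar < 1e-9))
      stop("mesh-quality error: degenerate deformed element")
    Gnew <- stepRes$ra$res$grad
    for (g in seq_len(nG)) {
      m <- system@materials[[g]]
      for (i in seq_along(m@pronyG))
        rState[[g]][[i]] <<- stepRes$eFac[[g]][[i]]["e"] * rState[[g]][[i]] +
          stepRes$eFac[[g]][[i]]["w"] * (Gnew[, g] - Gel[, g])
    }
    Gel <<- Gnew
    U <<- stepRes$U
    Fapp <- -stepRes$ra$st$G
    diag_$springWork <<- diag_$springWork +
      sum(0.5 * (Fapp + Fprev) * (U - Uprev))
    Uprev <<- U
    Fprev <<- Fapp
    tPrev <<- tk
    lastRes <<- stepRes
  }

  advanceTo <- function(tk, depth = 0) {
    stepRes <- tryStep(tk)
    if (is.null(stepRes)) {
      if (depth >= 10)
        stop(sprintf(
          "nonconvergence at t = %g s (last converged t = %g s)", tk, tPrev))
      tMid <- tPrev + (tk - tPrev) / 2
      advanceTo(tMid, depth + 1)
      advanceTo(tk, depth + 1)
    } else commit(stepRes, tk)
  }

  for (k in seq_along(schedule)) {
    tk <- schedule[k]
    advanceTo(tk)
    row <- k + 1L
    ra <- lastRes$ra
    openings[row, ] <- .openings(springs, ra$res$X)
    diag_$residual[row] <- sqrt(sum(ra$R[freeDof]^2)) / ra$fscale
    diag_$balance[row] <- sqrt(sum(colSums(matrix(ra$R, ncol = 3,
                                                  byrow = TRUE))^2)) /
      ra$fscale
    diag_$strainEnergy[row] <- sum(ra$res$energy)
    diag_$iterations[row] <- lastRes$it
    if (abs(tk - tRamp) < 1e-9)
      snapshots$POSTOP <- matrix(U, ncol = 3,
                                 byrow = TRUE)[seq_len(system@nReal), ]
    if (k == length(schedule))
      snapshots$FU <- matrix(U, ncol = 3,
                             byrow = TRUE)[seq_len(system@nReal), ]
    if (ctl$verbose)
      message(sprintf("t = %10.1f s  opening %s  (%d it)", tk,
                      paste(sprintf("%.2f", openings[row, ]),
                            collapse = " "), lastRes$it))
  }

  mono <- apply(openings, 2, cummax)
  if (any(openings < mono - 1e-5))
    warning("openings decreased along the schedule beyond solver tolerance")
  fl <- attr(system, "faceLabels")
  if (is.null(fl)) fl <- character(0)
  meshes <- lapply(snapshots, function(D)
    triSurface(system@X0[seq_len(system@nReal), , drop = FALSE] + D,
               system@faces, character(0), fl))
  new("ExpansionSolution", timePoints = tps, openings = openings,
      displacements = snapshots, deformedMeshes = meshes,
      springs = springs, diagnostics = diag_)
}

#' Extract the clinical report from an expansion solution
#'
#' Per-spring openings in mm and as % of the nominal 60 mm at POSTOP
#' (t = 1 s) and FU (t = 5 days), and BPD/OFD/cephalic index of the
#' deformed shell at PREOP, POSTOP and FU.
#'
#' @param solution an [ExpansionSolution-class].
#' @param frame the model's [AnatomicalFrame-class].
#' @return list with data.frames `openings` and `metrics`, and the solver
#'   `diagnostics`.
#' @export
extractOutputs <- function(solution, frame) {
  tp <- solution@timePoints
  need <- c(POSTOP = 1, FU = 432000)
  idx <- vapply(need, function(tt) {
    i <- which(abs(tp - tt) < 1e-6)
    if (!length(i)) stop(sprintf(
      "report error: missing timepoint t = %g s", tt))
    i[1]
  }, 1L)
  sp <- solution@springs
  spNames <- if (!is.null(names(sp))) names(sp)
             else paste0("spring", seq_along(sp))
  openings <- data.frame(
    spring = spNames,
    model = vapply(sp, function(s) s@modelId, ""),
    POSTOP_mm = solution@openings[idx["POSTOP"], ],
    POSTOP_pct = springOpeningPercent(solution@openings[idx["POSTOP"], ]),
    FU_mm = solution@openings[idx["FU"], ],
    FU_pct = springOpeningPercent(solution@openings[idx["FU"], ]),
    row.names = NULL)
  metrics <- do.call(rbind, lapply(names(solution@deformedMeshes),
    function(nm) {
      sm <- shapeMetrics(solution@deformedMeshes[[nm]], frame)
      data.frame(timepoint = nm, bpd = sm@bpd, ofd = sm@ofd, ci = sm@ci)
    }))
  list(openings = openings, metrics = metrics,
       diagnostics = solution@diagnostics)
}
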