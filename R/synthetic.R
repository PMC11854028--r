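# Deterministic synthetic phantoms: scaphocephalic head surfaces with
# analytic landmarks, two-layer skin/skull phantoms with known thickness,
# and small synthetic populations. These stand in for patient data, which
# is not distributable; they emulate the elongated, low-CI head shapes of
# the clinical cohort but none of the local anatomy (temporal fossae, ears,
# face) of real scans.

.sgnpow <- function(x, e) sign(x) * abs(x)^e

# geometry constants of the head phantom: the widest cross-section sits at
# 20% of the head height above the nasion-tragion plane (the superellipsoid
# centre), and the phantom extends 25% of the height below the plane.
.phantomGeom <- function(spec) {
  z0 <- 0.2 * spec@height
  list(aX = spec@bpd / 2, aY = spec@ofd / 2, z0 = z0,
       cUp = spec@height - z0, cLow = z0 + 0.25 * spec@height,
       e1 = spec@squareness[1], e2 = spec@squareness[2])
}

# implicit superellipsoid function; negative inside
.phantomImplicit <- function(p, g) {
  hor <- ((abs(p[1]) / g$aX)^(2 / g$e2) +
          (abs(p[2]) / g$aY)^(2 / g$e2))^(g$e2 / g$e1)
  cz <- if (p[3] >= g$z0) g$cUp else g$cLow
  hor + (abs(p[3] - g$z0) / cz)^(2 / g$e1) - 1
}

# first intersection of ray p0 + s*dir with the phantom surface (s > 0)
.phantomRayHit <- function(p0, dir, g) {
  f <- function(s) .phantomImplicit(p0 + s * dir, g)
  sHi <- 2 * (g$aY + g$cUp + g$cLow)
  if (f(0) >= 0 || f(sHi) <= 0) stop("ray does not leave the phantom")
  uniroot(f, c(0, sHi), tol = 1e-10)$root
}

#' Generate a scaphocephalic head phantom
#'
#' Builds a closed superellipsoidal head surface with the requested OFD,
#' BPD and height above the nasion-tragion plane, plus analytic landmarks:
#' nasion and tragions exactly on the base plane, bregma and lambda on the
#' midline where the configured suture planes meet the surface. The mesh is
#' deterministic for a given spec (optional Gaussian jitter is seeded).
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `mesh` ([TriSurface-class]) and `landmarks` (named list
#'   of numeric(3): nasion, tragion_left, tragion_right, bregma, lambda).
#' @examples
#' ph <- generateHead(phantomSpec(meshResolution = 8))
#' frame <- anatomicalFrame(ph$landmarks$nasion, ph$landmarks$tragion_left,
#'                          ph$landmarks$tragion_right, mesh = ph$mesh)
#' shapeMetrics(ph$mesh, frame)
#' @export
generateHead <- function(spec = phantomSpec()) {
  validObject(spec)
  g <- .phantomGeom(spec)
  rbar <- (g$aX + g$aY) / 2
  nu <- max(6L, as.integer(round(2 * pi * rbar / spec@meshResolution)))
  vArc <- pi / 2 * (rbar + (g$cUp + g$cLow) / 2)
  nv <- max(3L, as.integer(round(vArc / spec@meshResolution)))
  eta <- seq(-pi / 2, pi / 2, length.out = nv + 2)[2:(nv + 1)]
  omega <- seq(0, 2 * pi, length.out = nu + 1)[seq_len(nu)]

  ce <- .sgnpow(cos(eta), g$e1)
  se <- .sgnpow(sin(eta), g$e1)
  cz <- ifelse(eta >= 0, g$cUp, g$cLow)
  co <- .sgnpow(cos(omega), g$e2)
  so <- .sgnpow(sin(omega), g$e2)
  V <- cbind(g$aX * as.vector(outer(co, ce)),
             g$aY * as.vector(outer(so, ce)),
             g$z0 + rep(cz * se, each = nu))
  id <- function(i, j) (j - 1L) * nu + ((i - 1L) %% nu) + 1L # i wraps
  Fl <- vector("list", nv + 1)
  for (j in seq_len(nv - 1)) {
    i <- seq_len(nu)
    Fl[[j]] <- rbind(cbind(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
                     cbind(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  bot <- nrow(V) + 1L; top <- nrow(V) + 2L
  V <- rbind(V, c(0, 0, g$z0 - g$cLow), c(0, 0, g$z0 + g$cUp))
  i <- seq_len(nu)
  Fl[[nv]] <- cbind(id(i + 1, 1), id(i, 1), bot)
  Fl[[nv + 1]] <- cbind(id(i, nv), id(i + 1, nv), top)
  F <- do.call(rbind, Fl)
  if (spec@jitter > 0) {
    set.seed(spec@seed)
    V <- V + matrix(rnorm(length(V), 0, spec@jitter), ncol = 3)
  }
  mesh <- ensureOutward(triSurface(V, F))
  if (nFaces(mesh) < 50)
    stop("spec error: mesh resolution too coarse (< 50 faces)")

  # landmarks
  sinb <- -(g$z0 / g$cLow)^(1 / g$e1)
  s0 <- .sgnpow(sqrt(1 - sinb^2), g$e1)
  nasion <- c(0, g$aY * s0, 0)
  trL <- c(-g$aX * s0, 0, 0)
  trR <- c(g$aX * s0, 0, 0)
  A <- nasion; P <- c(0, -g$aY * s0, 0)
  su <- spec@suture
  B <- A + su@abFrac * (P - A)
  L <- P - su@lpFrac * (P - A)
  aRad <- su@alpha * pi / 180
  bRad <- su@beta * pi / 180
  dirB <- c(0, cos(aRad), sin(aRad))   # toward A, tilted cranially
  dirL <- c(0, -cos(bRad), sin(bRad))  # toward P, tilted cranially
  bregma <- B + .phantomRayHit(B, dirB, g) * dirB
  lambda <- L + .phantomRayHit(L, dirL, g) * dirL
  list(mesh = mesh,
       landmarks = list(nasion = nasion, tragion_left = trL,
                        tragion_right = trR, bregma = bregma,
                        lambda = lambda))
}

#' Generate a two-layer skin/skull phantom
#'
#' The skin surface is the head phantom; the outer skull table is its inward
#' offset by the skin thickness, and the inner table the further offset by
#' the skull thickness. Layer thicknesses are therefore known exactly by
#' construction, which makes this the test bed for the surface-distance
#' thickness measurement.
#'
#' @param spec a [PhantomSpec-class].
#' @return list with `skin`, `skullOuter`, `skullInner`
#'   ([TriSurface-class]), plus the `landmarks` of the head phantom.
#' @export
generateTwoLayer <- function(spec = phantomSpec()) {
  ph <- generateHead(spec)
  skullOuter <- offsetInward(ph$mesh, spec@skinThickness)
  skullInner <- offsetInward(skullOuter, spec@skullThickness)
  list(skin = ph$mesh, skullOuter = skullOuter, skullInner = skullInner,
       landmarks = ph$landmarks)
}

#' Default population parameter distributions
#'
#' Normal distributions centred on the published cohort averages: scalp
#' 2.8 +/- 0.4 mm, skull 2.5 +/- 0.4 mm, coronal angle 83 +/- 4 deg,
#' lambdoid angle 68 +/- 3 deg. Head dimensions and foot ratios have no
#' published spread and carry package-chosen sds.
#'
#' @return named list of c(mean, sd) pairs.
#' @export
defaultPopulationDistributions <- function() {
  list(ofd = c(125, 6), bpd = c(96, 5), height = c(80, 4),
       skinThickness = c(2.8, 0.4), skullThickness = c(2.5, 0.4),
       alpha = c(83, 4), beta = c(68, 3),
       abFrac = c(0.30, 0.02), lpFrac = c(0.25, 0.02))
}

#' Generate a synthetic population of phantom specs
#'
#' Reproducible normal draws of the phantom parameters, clamped into their
#' validity ranges (and bpd forced below ofd to keep every phantom
#' scaphocephalic).
#'
#' @param n number of subjects, >= 1.
#' @param distributions named list of c(mean, sd); see
#'   [defaultPopulationDistributions()].
#' @param seed integer RNG seed.
#' @param meshResolution target edge length passed to every spec (mm).
#' @return list of [PhantomSpec-class].
#' @export
generatePopulation <- function(n, distributions =
                                 defaultPopulationDistributions(),
                               seed = 1L, meshResolution = 6) {
  if (n < 1) stop("input error: n must be >= 1")
  base <- defaultPopulationDistributions()
  distributions <- modifyList(base, distributions)
  for (nm in names(distributions)) {
    d <- distributions[[nm]]
    if (length(d) != 2 || d[2] < 0 || !all(is.finite(d)))
      stop(sprintf("input error: invalid distribution for %s", nm))
  }
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    dr <- vapply(distributions, function(d) rnorm(1, d[1], d[2]), 1)
    dr["bpd"] <- min(dr["bpd"], 0.95 * dr["ofd"])
    clamp <- function(x, lo, hi) min(max(x, lo), hi)
    phantomSpec(ofd = max(dr["ofd"], 60), bpd = max(dr["bpd"], 40),
                height = max(dr["height"], 40),
                skinThickness = clamp(dr["skinThickness"], 0.5, 10),
                skullThickness = clamp(dr["skullThickness"], 0.5, 10),
                suture = sutureGeometry(
                  alpha = clamp(dr["alpha"], 30, 150),
                  beta = clamp(dr["beta"], 30, 150),
                  abFrac = clamp(dr["abFrac"], 0.1, 0.45),
                  lpFrac = clamp(dr["lpFrac"], 0.1, 0.45)),
                meshResolution = meshResolution, seed = seed + i)
  })
}
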