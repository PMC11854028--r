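# Measurement operators: surface-distance thickness, suture geometry,
# population averaging, cranial shape metrics.

#' Local surface-distance thickness between two surfaces
#'
#' For every vertex of `surfaceA` above the crop plane, computes the
#' unsigned nearest-point distance to `surfaceB` (point-to-triangle, not a
#' normal-ray intersection, which is fragile on noisy scans). This realises
#' both the scalp thickness (skin vs outer skull table) and the skull
#' thickness (outer vs inner table) measurements; the crop plane excludes
#' the skull base and orbits.
#'
#' @param surfaceA,surfaceB [TriSurface-class] objects.
#' @param cropPlane a [Plane-class]; only vertices of `surfaceA` on its
#'   positive side are measured (see [cropPlaneAtFraction()]).
#' @return a [ThicknessMap-class].
#' @examples
#' tl <- generateTwoLayer(phantomSpec(meshResolution = 8))
#' cp <- cropPlaneAtFraction(tl$skin, fitBasePlane(c(0, 55, 0),
#'   c(-45, 0, 0), c(45, 0, 0)), 0.25)
#' thicknessBetween(tl$skin, tl$skullOuter, cp)
#' @export
thicknessBetween <- function(surfaceA, surfaceB, cropPlane) {
  if (nFaces(surfaceA) == 0 || nFaces(surfaceB) == 0)
    stop("both surfaces must be non-empty")
  d <- signedDistance(cropPlane, surfaceA@vertices)
  sel <- d >= 0
  if (!any(sel)) stop("empty-measurement error: no vertices above crop plane")
  pts <- surfaceA@vertices[sel, , drop = FALSE]
  dist <- .cppNearestSurfaceDistance(pts, surfaceB@vertices, surfaceB@faces)
  new("ThicknessMap", distances = dist, mean = mean(dist),
      sd = if (length(dist) > 1) sd(dist) else 0, cropPlane = cropPlane)
}

#' Crop plane at a fraction of skull height
#'
#' Returns the plane parallel to the base plane, raised by
#' `fraction x (maximum vertex height above the base plane)`. Thickness
#' measurements use fraction 0.25 so the lower quarter of the skull (base,
#' orbits) is excluded.
#'
#' @param mesh a [TriSurface-class].
#' @param basePlane the nasion-tragion [Plane-class].
#' @param fraction height fraction in `[0, 1)`.
#' @return a [Plane-class].
#' @export
cropPlaneAtFraction <- function(mesh, basePlane, fraction) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  h <- signedDistance(basePlane, mesh@vertices)
  hmax <- max(h)
  if (hmax <= 0) stop("geometry error: mesh entirely below base plane")
  plane(basePlane@point + fraction * hmax * basePlane@normal,
        basePlane@normal)
}

# polyline of the mesh/plane section: intersection points of crossing edges
.planeSection <- function(mesh, plane) {
  v <- mesh@vertices; f <- mesh@faces
  d <- signedDistance(plane, v)
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  di <- d[ed[, 1]]; dj <- d[ed[, 2]]
  cr <- di * dj < 0
  pts <- NULL
  if (any(cr)) {
    t <- di[cr] / (di[cr] - dj[cr])
    pts <- v[ed[cr, 1], , drop = FALSE] +
      t * (v[ed[cr, 2], , drop = FALSE] - v[ed[cr, 1], , drop = FALSE])
  }
  on <- abs(d) < 1e-9
  if (any(on)) pts <- rbind(pts, v[on, , drop = FALSE])
  pts
}

#' Find the anterior and posterior extreme points A and P
#'
#' A and P are the most anterior and most posterior points of the
#' mesh-with-base-plane section; the anterior direction is the long
#' principal axis of the section, oriented toward the nasion. When the mesh
#' does not cross the plane (e.g. after an inward offset of an already-cut
#' surface), the open rim vertices nearest the plane are projected onto it
#' instead.
#'
#' @param mesh a [TriSurface-class].
#' @param basePlane the nasion-tragion [Plane-class].
#' @param anterior numeric(3): a point on the anterior side (the nasion).
#' @return list with `A` and `P` (numeric(3), on the plane).
#' @export
findAPPoints <- function(mesh, basePlane, anterior) {
  pts <- .planeSection(mesh, basePlane)
  if (is.null(pts) || nrow(pts) < 2) {
    # fall back to the boundary rim near the plane
    lps <- boundaryLoops(mesh)
    if (length(lps)) {
      rim <- unlist(lps)
      d <- abs(signedDistance(basePlane, mesh@vertices[rim, , drop = FALSE]))
      edgeLen <- sqrt(mean(faceAreas(mesh)) * 4 / sqrt(3))
      sel <- rim[d < max(3, 2 * edgeLen)]
      if (length(sel) >= 2) pts <- mesh@vertices[sel, , drop = FALSE]
    }
  }
  if (is.null(pts) || nrow(pts) < 2)
    stop("geometry error: empty base-plane section")
  # project onto the plane
  d <- signedDistance(basePlane, pts)
  pts <- pts - outer(d, basePlane@normal)
  ctr <- colMeans(pts)
  cpts <- sweep(pts, 2, ctr)
  pc <- eigen(crossprod(cpts), symmetric = TRUE)$vectors[, 1]
  if (sum(pc * (anterior - ctr)) < 0) pc <- -pc
  proj <- drop(cpts %*% pc)
  list(A = pts[which.max(proj), ], P = pts[which.min(proj), ])
}

#' Measure suture-plane geometry from an anatomical frame
#'
#' The coronal angle alpha is the point angle A-B-Bregma and the lambdoid
#' angle beta is P-L-Lambda, with B and L the feet of the suture planes on
#' segment AP; abFrac = |AB|/|AP|, lpFrac = |LP|/|AP|.
#'
#' @param frame an [AnatomicalFrame-class] carrying A, P, B, L, bregma and
#'   lambda.
#' @return a [SutureGeometry-class].
#' @export
measureSutureGeometry <- function(frame) {
  need <- c("A", "P", "B", "L", "bregma", "lambdaPt")
  for (nm in need)
    if (length(slot(frame, nm)) != 3)
      stop(sprintf("frame is missing %s", nm))
  ang <- function(u, v) {
    cu <- sqrt(sum(u^2)); cv <- sqrt(sum(v^2))
    if (cu < 1e-9 || cv < 1e-9)
      stop("geometry error: degenerate suture angle (landmark on AP line)")
    acos(pmin(1, pmax(-1, sum(u * v) / (cu * cv)))) * 180 / pi
  }
  apLen <- sqrt(sum((frame@P - frame@A)^2))
  alpha <- ang(frame@A - frame@B, frame@bregma - frame@B)
  beta <- ang(frame@P - frame@L, frame@lambdaPt - frame@L)
  new("SutureGeometry", alpha = alpha, beta = beta,
      abFrac = sqrt(sum((frame@B - frame@A)^2)) / apLen,
      lpFrac = sqrt(sum((frame@L - frame@P)^2)) / apLen)
}

#' Average measurements over a subject group
#'
#' Arithmetic mean (and standard deviation) of the per-subject scalp and
#' skull thickness means and suture geometry, giving the population
#' parameters used to build surface-scan models of subjects without CT.
#'
#' @param measurements list; each element a list with fields `skin` and
#'   `skull` ([ThicknessMap-class] or numeric) and `suture`
#'   ([SutureGeometry-class]).
#' @param sutureWidth assumed suture band width (mm).
#' @return a [PopulationParams-class] with the `sds` slot filled.
#' @export
populationAverage <- function(measurements, sutureWidth = 2) {
  if (!length(measurements)) stop("input error: empty measurement list")
  num <- function(x) if (is(x, "ThicknessMap")) x@mean else as.numeric(x)
  tab <- vapply(measurements, function(m) c(
    skin = num(m$skin), skull = num(m$skull),
    alpha = m$suture@alpha, beta = m$suture@beta,
    abFrac = m$suture@abFrac, lpFrac = m$suture@lpFrac), numeric(6))
  mu <- rowMeans(tab)
  sds <- apply(tab, 1, function(r) if (length(r) > 1) sd(r) else 0)
  populationParams(skinThickness = mu[["skin"]],
                   skullThickness = mu[["skull"]],
                   suture = new("SutureGeometry", alpha = mu[["alpha"]],
                                beta = mu[["beta"]], abFrac = mu[["abFrac"]],
                                lpFrac = mu[["lpFrac"]]),
                   sutureWidth = sutureWidth, sds = sds)
}

#' Cranial shape metrics: BPD, OFD, cephalic index
#'
#' OFD is the maximal extent of the supra-base-plane surface along the AP
#' axis, BPD the maximal extent perpendicular to the midline plane, and
#' CI = BPD / OFD: the standard cephalometric convention, applied to the
#' mesh vertices above the base plane.
#'
#' @param mesh a [TriSurface-class].
#' @param frame an [AnatomicalFrame-class].
#' @return a [ShapeMetrics-class].
#' @export
shapeMetrics <- function(mesh, frame) {
  d <- signedDistance(frame@basePlane, mesh@vertices)
  sel <- d >= -1e-6
  if (!any(sel)) stop("geometry error: no vertices above base plane")
  v <- mesh@vertices[sel, , drop = FALSE]
  ax <- .frameAxes(frame)
  ofd <- diff(range(v %*% ax$apHat))
  bpd <- diff(range(v %*% ax$lat))
  new("ShapeMetrics", bpd = bpd, ofd = ofd, ci = bpd / ofd)
}

# total length of the mesh/plane intersection curve
.planeSectionLength <- function(mesh, plane) {
  v <- mesh@vertices; f <- mesh@faces
  d <- signedDistance(plane, v)
  len <- 0
  smat <- matrix(sign(d)[f], ncol = 3)
  crossing <- which(apply(smat, 1, max) > 0 & apply(smat, 1, min) < 0)
  for (r in crossing) {
    tri <- f[r, ]
    pts <- NULL
    for (k in 1:3) {
      i <- tri[k]; j <- tri[(k %% 3) + 1]
      if (d[i] * d[j] < 0) {
        t <- d[i] / (d[i] - d[j])
        pts <- rbind(pts, v[i, ] + t * (v[j, ] - v[i, ]))
      } else if (d[i] == 0) pts <- rbind(pts, v[i, ])
    }
    if (!is.null(pts) && nrow(pts) >= 2)
      len <- len + sqrt(sum((pts[2, ] - pts[1, ])^2))
  }
  len
}

#' Measured geodesic width of a suture band
#'
#' Band area divided by the length of the suture mid-curve (the section of
#' the shell with the suture plane): a robust estimate of the geodesic band
#' width.
#'
#' @param model a [SkullModel-class].
#' @param which "coronal_suture" or "lambdoid_suture".
#' @return numeric(1), mm.
#' @export
measureSutureBandWidth <- function(model,
                                   which = c("coronal_suture",
                                             "lambdoid_suture")) {
  which <- match.arg(which)
  shell <- model@shell
  sel <- shell@faceLabels == which
  if (!any(sel)) stop("suture band is empty")
  band <- triSurface(shell@vertices, shell@faces[sel, , drop = FALSE])
  pl <- if (which == "coronal_suture") model@coronalPlane
        else model@lambdoidPlane
  len <- .planeSectionLength(band, pl)
  if (len <= 0) stop("suture plane does not intersect its band")
  meshArea(band) / len
}

#' Spring opening as a percentage of the nominal size
#'
#' All spring openings are expressed as a percentage of the 60 mm nominal
#' fully-open length of the clinical distractors.
#'
#' @param opening numeric, mm, `>= 0`.
#' @param nominal nominal size, mm (default 60).
#' @return numeric, percent.
#' @examples
#' springOpeningPercent(42) # 70
#' @export
springOpeningPercent <- function(opening, nominal = 60) {
  if (nominal <= 0) stop("config error: nominal must be > 0")
  if (any(opening < 0)) stop("opening must be >= 0")
  100 * opening / nominal
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation between two series (e.g. cephalic indices of two model
#' families over the same subjects). For n <= 9 without ties the p-value is
#' computed from the exact permutation distribution; otherwise the
#' t-approximation is used.
#'
#' @param seriesA,seriesB numeric vectors of equal length >= 3.
#' @return list with `rho` and `p`.
#' @export
spearmanRho <- function(seriesA, seriesB) {
  if (length(seriesA) != length(seriesB)) stop("series lengths differ")
  n <- length(seriesA)
  if (n < 3) stop("need at least 3 observations")
  if (sd(seriesA) == 0 || sd(seriesB) == 0)
    stop("undefined-correlation error: constant series")
  ra <- rank(seriesA); rb <- rank(seriesB)
  rho <- unname(cor(ra, rb))
  noTies <- !anyDuplicated(ra) && !anyDuplicated(rb)
  if (n <= 9 && noTies) {
    # exact permutation distribution: rho under permutation of one ranking
    # depends only on S = sum of squared rank differences
    perms <- .allPermutations(n)
    S <- colSums((t(perms) - seq_len(n))^2)
    rhoAll <- 1 - 6 * S / (n * (n^2 - 1))
    p <- mean(abs(rhoAll) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p)
}

# all permutations of 1..n as an n!-row matrix (n <= 9)
.allPermutations <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- .allPermutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(rep(i, nrow(p)), p + (p >= i))))
}
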