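# Triangle-mesh surgery: basic differential quantities, plane cutting,
# inward offsetting, hole filling, inner/outer separation. All tolerances in
# mm; geometric coincidence tolerance is 1e-6 mm.

.COINC_TOL <- 1e-6

.rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise zero vector")
  v / n
}

.faceCross <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  .rowCross(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
            v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
}

#' Per-face areas of a mesh
#' @param mesh a [TriSurface-class].
#' @return numeric vector of face areas (mm^2).
#' @export
faceAreas <- function(mesh) {
  if (nFaces(mesh) == 0) return(numeric(0))
  0.5 * sqrt(rowSums(.faceCross(mesh)^2))
}

#' Per-face unit normals
#' @param mesh a [TriSurface-class].
#' @return numeric `m x 3` matrix.
#' @export
faceNormals <- function(mesh) {
  cr <- .faceCross(mesh)
  cr / sqrt(rowSums(cr^2))
}

.faceCentroids <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' Total surface area
#' @param mesh a [TriSurface-class].
#' @return numeric(1), mm^2.
#' @export
meshArea <- function(mesh) sum(faceAreas(mesh))

#' Signed enclosed volume (positive for outward-oriented closed meshes)
#' @param mesh a [TriSurface-class].
#' @return numeric(1), mm^3.
#' @export
signedVolume <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * .rowCross(b, cc))) / 6
}

#' Angle-weighted per-vertex normals
#'
#' Angle weighting makes the normal of a tessellated smooth surface converge
#' to the true surface normal, which the inward-offset construction relies
#' on.
#'
#' @param mesh a [TriSurface-class].
#' @return numeric `n x 3` matrix of unit normals.
#' @export
vertexNormals <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  fn <- faceNormals(mesh)
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    i0 <- f[, k]; i1 <- f[, (k %% 3) + 1]; i2 <- f[, ((k + 1) %% 3) + 1]
    e1 <- v[i1, , drop = FALSE] - v[i0, , drop = FALSE]
    e2 <- v[i2, , drop = FALSE] - v[i0, , drop = FALSE]
    cosang <- rowSums(e1 * e2) /
      (sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)))
    ang <- acos(pmin(1, pmax(-1, cosang)))
    acc <- rowsum(fn * ang, group = i0)
    idx <- as.integer(rownames(acc))
    n[idx, ] <- n[idx, ] + acc
  }
  n / sqrt(rowSums(n^2))
}

# undirected edge table: one row per undirected edge with adjacent faces
.meshEdges <- function(mesh) {
  f <- mesh@faces
  m <- nrow(f)
  he <- rbind(cbind(f[, 1], f[, 2], f[, 3], seq_len(m)),
              cbind(f[, 2], f[, 3], f[, 1], seq_len(m)),
              cbind(f[, 3], f[, 1], f[, 2], seq_len(m)))
  colnames(he) <- c("from", "to", "opp", "face")
  n <- nVertices(mesh)
  key <- pmin(he[, 1], he[, 2]) * (n + 1) + pmax(he[, 1], he[, 2])
  ord <- order(key)
  he <- he[ord, , drop = FALSE]
  key <- key[ord]
  grp <- cumsum(c(TRUE, diff(key) != 0))
  cnt <- tabulate(grp)
  if (any(cnt > 2)) stop("non-manifold edge (more than two adjacent faces)")
  list(he = he, grp = grp, cnt = cnt)
}

#' Open boundary loops of a mesh
#'
#' @param mesh a [TriSurface-class].
#' @return list of integer vectors, each an ordered loop of vertex indices.
#'   Errors on non-manifold input.
#' @export
boundaryLoops <- function(mesh) {
  me <- .meshEdges(mesh)
  bidx <- which(me$cnt == 1)
  if (!length(bidx)) return(list())
  firsts <- c(1L, which(diff(me$grp) != 0) + 1L)
  bhe <- me$he[firsts[bidx], , drop = FALSE]
  # walk directed boundary half-edges from -> to
  nxt <- new.env(hash = TRUE)
  for (r in seq_len(nrow(bhe)))
    assign(as.character(bhe[r, 1]), bhe[r, 2], envir = nxt)
  if (length(ls(nxt)) != nrow(bhe))
    stop("non-manifold boundary (vertex on more than one boundary edge pair)")
  visited <- new.env(hash = TRUE)
  loops <- list()
  for (r in seq_len(nrow(bhe))) {
    s <- bhe[r, 1]
    if (!is.null(visited[[as.character(s)]])) next
    loop <- integer(0)
    cur <- s
    repeat {
      loop <- c(loop, cur)
      assign(as.character(cur), TRUE, envir = visited)
      nx <- nxt[[as.character(cur)]]
      if (is.null(nx)) stop("open (non-loop) boundary: non-manifold input")
      cur <- nx
      if (cur == s) break
      if (length(loop) > nrow(bhe)) stop("boundary walk failed")
    }
    loops[[length(loops) + 1]] <- loop
  }
  loops
}

#' Signed distances from points to a plane
#' @param plane a [Plane-class].
#' @param points numeric `n x 3` matrix.
#' @return numeric vector of signed distances (mm), positive on the normal
#'   side.
#' @export
signedDistance <- function(plane, points) {
  points <- rbind(points)
  drop((points - matrix(plane@point, nrow(points), 3, byrow = TRUE)) %*%
         plane@normal)
}

#' Apply a rigid (or affine) transform to a mesh
#' @param mesh a [TriSurface-class].
#' @param rotation 3x3 matrix.
#' @param translation numeric(3).
#' @return transformed [TriSurface-class].
#' @export
transformMesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0)) {
  v <- mesh@vertices %*% t(rotation)
  v <- sweep(v, 2, -as.numeric(translation))
  triSurface(v, mesh@faces, mesh@vertexLabels, mesh@faceLabels)
}

#' Transform a plane by the same rigid transform
#' @param pl a [Plane-class].
#' @param rotation 3x3 matrix.
#' @param translation numeric(3).
#' @return transformed [Plane-class].
#' @export
transformPlane <- function(pl, rotation = diag(3), translation = c(0, 0, 0)) {
  plane(drop(rotation %*% pl@point) + as.numeric(translation),
        drop(rotation %*% pl@normal))
}

# drop vertices not referenced by any face, reindex faces
.dropUnusedVertices <- function(vertices, faces, vertexLabels = character(0),
                                faceLabels = character(0)) {
  used <- sort(unique(as.vector(faces)))
  map <- integer(nrow(vertices))
  map[used] <- seq_along(used)
  f2 <- matrix(map[faces], ncol = 3)
  vl <- if (length(vertexLabels)) vertexLabels[used] else character(0)
  triSurface(vertices[used, , drop = FALSE], f2, vl, faceLabels)
}

# Core plane-splitting walker. Splits every face crossing the plane, and
# returns the split mesh plus per-face mean signed distance. keep = "positive",
# "negative" or "both".
# window: optional function(point3) -> logical restricting where edges are
# actually cut (used for finite osteotomy cuts). The decision depends only
# on the intersection point, so the two faces sharing an edge always agree
# and no T-junctions arise. Requires keep = "both"; partially cut faces are
# re-triangulated as a single fan from the first cut point.
.planeSplit <- function(mesh, plane, keep, faceMask = NULL, snapFrac = 0,
                        window = NULL) {
  v <- mesh@vertices
  f <- mesh@faces
  hasVL <- length(mesh@vertexLabels) > 0
  hasFL <- length(mesh@faceLabels) > 0
  d <- signedDistance(plane, v)
  d[abs(d) < .COINC_TOL] <- 0
  if (snapFrac > 0) {
    # treat vertices much closer to the plane than their shortest incident
    # edge as lying on it: a globally consistent way to avoid slivers
    idx <- integer(0); val <- numeric(0)
    for (k in 1:3) {
      i <- f[, k]; j <- f[, (k %% 3) + 1]
      el <- sqrt(rowSums((v[i, , drop = FALSE] - v[j, , drop = FALSE])^2))
      idx <- c(idx, i, j); val <- c(val, el, el)
    }
    agg <- tapply(val, idx, min)
    minEdge <- rep(Inf, nrow(v))
    minEdge[as.integer(names(agg))] <- agg
    d[abs(d) < snapFrac * minEdge] <- 0
  }

  sgn <- sign(d)
  smat <- matrix(sgn[f], ncol = 3)
  crossing <- (apply(smat, 1, max) > 0) & (apply(smat, 1, min) < 0)
  if (!is.null(faceMask)) {
    stopifnot(keep == "both") # masked splitting never discards faces
    crossing <- crossing & faceMask
  }
  if (!is.null(window)) stopifnot(keep == "both")

  newV <- list()
  edgeKey <- new.env(hash = TRUE)
  nv0 <- nrow(v)
  getCut <- function(i, j) {
    kk <- paste(min(i, j), max(i, j))
    id <- edgeKey[[kk]]
    if (!is.null(id)) return(id)
    t <- d[i] / (d[i] - d[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    if (!is.null(window) && !window(p)) {
      assign(kk, NA_integer_, envir = edgeKey)
      return(NA_integer_)
    }
    newV[[length(newV) + 1]] <<- p
    id <- nv0 + length(newV)
    assign(kk, id, envir = edgeKey)
    id
  }

  outF <- vector("list", nrow(f))
  outL <- vector("list", nrow(f))
  unsplit <- logical(nrow(f))
  for (r in which(crossing)) {
    tri <- f[r, ]
    if (is.null(window)) {
      polyPos <- integer(0); polyNeg <- integer(0)
      for (k in 1:3) {
        i <- tri[k]; j <- tri[(k %% 3) + 1]
        if (sgn[i] >= 0) polyPos <- c(polyPos, i)
        if (sgn[i] <= 0) polyNeg <- c(polyNeg, i)
        if (sgn[i] * sgn[j] < 0) {
          cid <- getCut(i, j)
          polyPos <- c(polyPos, cid)
          polyNeg <- c(polyNeg, cid)
        }
      }
      fans <- list()
      if (keep %in% c("positive", "both") && length(polyPos) >= 3)
        fans <- c(fans, lapply(2:(length(polyPos) - 1), function(k)
          c(polyPos[1], polyPos[k], polyPos[k + 1])))
      if (keep %in% c("negative", "both") && length(polyNeg) >= 3)
        fans <- c(fans, lapply(2:(length(polyNeg) - 1), function(k)
          c(polyNeg[1], polyNeg[k], polyNeg[k + 1])))
    } else {
      # windowed cut: single polygon around the face with cut points
      # inserted on the cut edges; fan from the first cut point
      poly <- integer(0); firstCut <- NA_integer_
      for (k in 1:3) {
        i <- tri[k]; j <- tri[(k %% 3) + 1]
        poly <- c(poly, i)
        if (sgn[i] * sgn[j] < 0) {
          cid <- getCut(i, j)
          if (!is.na(cid)) {
            poly <- c(poly, cid)
            if (is.na(firstCut)) firstCut <- length(poly)
          }
        }
      }
      if (is.na(firstCut)) {
        unsplit[r] <- TRUE
        next
      }
      poly <- c(poly[firstCut:length(poly)], poly[seq_len(firstCut - 1)])
      fans <- lapply(2:(length(poly) - 1), function(k)
        c(poly[1], poly[k], poly[k + 1]))
    }
    if (length(fans)) {
      outF[[r]] <- do.call(rbind, fans)
      if (hasFL) outL[[r]] <- rep(mesh@faceLabels[r], length(fans))
    }
  }

  rmin <- apply(smat, 1, min); rmax <- apply(smat, 1, max)
  keepWhole <- !crossing & switch(keep,
    positive = rmin >= 0,
    negative = rmax <= 0,
    both = rep(TRUE, nrow(f)))
  keepWhole <- keepWhole | unsplit

  fw <- f[keepWhole, , drop = FALSE]
  lw <- if (hasFL) mesh@faceLabels[keepWhole] else character(0)
  fs <- do.call(rbind, outF[!vapply(outF, is.null, TRUE)])
  ls_ <- if (hasFL) unlist(outL[!vapply(outL, is.null, TRUE)]) else character(0)
  f2 <- rbind(fw, fs)
  if (is.null(f2) || nrow(f2) == 0) stop("cut leaves empty mesh")
  l2 <- if (hasFL) c(lw, ls_) else character(0)

  vAll <- rbind(v, do.call(rbind, newV))
  vlAll <- if (hasVL) c(mesh@vertexLabels, rep("", length(newV)))
           else character(0)
  # drop degenerate slivers created by snapping
  a <- rbind(vAll[f2[, 1], ]); b <- rbind(vAll[f2[, 2], ]); cc <- rbind(vAll[f2[, 3], ])
  ar <- 0.5 * sqrt(rowSums(.rowCross(b - a, cc - a)^2))
  good <- ar > 1e-10
  f2 <- f2[good, , drop = FALSE]
  if (hasFL) l2 <- l2[good]
  if (nrow(f2) == 0) stop("cut leaves empty mesh")
  .dropUnusedVertices(vAll, f2, vlAll, l2)
}

#' Cut a mesh by a plane
#'
#' Removes all geometry on one side of the plane; triangles straddling the
#' plane are split so the open boundary lies exactly on the plane. This is
#' the operation used to trim head and skull models at the nasion-tragion
#' plane.
#'
#' @param mesh a [TriSurface-class].
#' @param plane a [Plane-class].
#' @param keep "positive" (the side the normal points to) or "negative".
#' @return the trimmed [TriSurface-class]; face labels are inherited by split
#'   faces.
#' @examples
#' sph <- generateHead(phantomSpec(meshResolution = 8))$mesh
#' upper <- cutByPlane(sph, plane(c(0, 0, 0), c(0, 0, 1)), "positive")
#' @export
cutByPlane <- function(mesh, plane, keep = c("positive", "negative")) {
  keep <- match.arg(keep)
  d <- signedDistance(plane, mesh@vertices)
  d[abs(d) < .COINC_TOL] <- 0
  if (keep == "positive" && all(d >= 0)) return(mesh)
  if (keep == "negative" && all(d <= 0)) return(mesh)
  .planeSplit(mesh, plane, keep)
}

#' Split faces crossing a plane without discarding either side
#' @param mesh a [TriSurface-class].
#' @param plane a [Plane-class].
#' @param snapFrac edge-parameter snapping tolerance: intersections within
#'   this fraction of an edge's length from an endpoint reuse the endpoint
#'   instead of creating a sliver.
#' @return a [TriSurface-class] with crossing faces split.
#' @export
splitByPlane <- function(mesh, plane, snapFrac = 0)
  .planeSplit(mesh, plane, "both", snapFrac = snapFrac)

#' Ensure outward orientation of a closed mesh
#'
#' Flips all faces if the signed enclosed volume is negative.
#' @param mesh a closed [TriSurface-class].
#' @return consistently outward-oriented mesh.
#' @export
ensureOutward <- function(mesh) {
  if (signedVolume(mesh) < 0)
    mesh@faces <- mesh@faces[, c(1, 3, 2)]
  mesh
}

#' Offset a surface inward along vertex normals
#'
#' Displaces every vertex by `distance` along the inward (anti-normal)
#' direction; this derives an estimated outer skull surface from a head
#' surface given the population-average scalp thickness.
#'
#' @param mesh a [TriSurface-class] with outward orientation (closed meshes
#'   are re-oriented automatically).
#' @param distance offset in mm, `>= 0`.
#' @return the offset [TriSurface-class]; topology is preserved.
#' @examples
#' head <- generateHead(phantomSpec(meshResolution = 8))$mesh
#' skull <- offsetInward(head, 2.8)
#' @export
offsetInward <- function(mesh, distance) {
  if (distance < 0) stop("distance must be >= 0")
  if (distance == 0) return(mesh)
  closed <- length(boundaryLoops(mesh)) == 0
  if (closed) mesh <- ensureOutward(mesh)
  n <- vertexNormals(mesh)
  out <- mesh
  out@vertices <- mesh@vertices - distance * n
  newAr <- faceAreas(out)
  if (any(newAr <= 1e-9))
    stop("offset-failure: offset exceeds local feature size (collapsed faces)")
  fn0 <- faceNormals(mesh); fn1 <- faceNormals(out)
  if (mean(rowSums(fn0 * fn1)) < 0)
    stop("offset-failure: global orientation flip")
  if (closed && signedVolume(out) <= 0)
    stop("offset-failure: offset exceeds local feature size (volume collapse)")
  out
}

#' Close open boundary loops by fan triangulation
#'
#' Automated replacement for the manual suture/defect filling step: every
#' open boundary loop (other than loops lying on an exempt plane, typically
#' the base rim) is closed with a fan around the loop centroid.
#'
#' @param mesh a [TriSurface-class].
#' @param keepOpen optional [Plane-class]: loops whose vertices all lie
#'   within `tol` of this plane are left open.
#' @param tol coincidence tolerance for the exempt plane test (mm).
#' @return a [TriSurface-class] with the non-exempt loops closed.
#' @export
closeHoles <- function(mesh, keepOpen = NULL, tol = 1) {
  mesh <- .splitPinchVertices(mesh) # tolerate bowtie boundary vertices
  loops <- boundaryLoops(mesh)
  if (!length(loops)) return(mesh)
  keep <- if (is.null(keepOpen)) rep(FALSE, length(loops))
          else vapply(loops, function(l)
            all(abs(signedDistance(keepOpen,
                                   mesh@vertices[l, , drop = FALSE])) < tol),
            TRUE)
  .fillLoops(mesh, loops[!keep], label = "fill")
}

# fan-triangulate the given boundary loops around their centroids
.fillLoops <- function(mesh, loops, label = "fill") {
  if (!length(loops)) return(mesh)
  v <- mesh@vertices
  f <- mesh@faces
  hasVL <- length(mesh@vertexLabels) > 0
  hasFL <- length(mesh@faceLabels) > 0
  vl <- mesh@vertexLabels
  fl <- mesh@faceLabels
  for (loop in loops) {
    nl <- length(loop)
    # boundary loop traversal follows boundary half-edge direction; cap
    # faces must be oriented opposite to it for consistency
    if (nl == 3) {
      capf <- rbind(rev(loop))
    } else if (nl == 4) {
      r <- rev(loop)
      d13 <- sum((v[r[1], ] - v[r[3], ])^2)
      d24 <- sum((v[r[2], ] - v[r[4], ])^2)
      capf <- if (d13 <= d24) rbind(r[c(1, 2, 3)], r[c(1, 3, 4)])
              else rbind(r[c(2, 3, 4)], r[c(2, 4, 1)])
    } else {
      ctr <- colMeans(v[loop, , drop = FALSE])
      v <- rbind(v, ctr)
      cid <- nrow(v)
      if (hasVL) vl <- c(vl, "")
      capf <- cbind(loop[c(2:nl, 1)], loop, cid)
    }
    f <- rbind(f, capf)
    if (hasFL) fl <- c(fl, rep(label, nrow(capf)))
  }
  out <- triSurface(v, f, vl, fl)
  .meshEdges(out) # errors if the result is not edge-manifold
  out
}

# Split non-manifold "pinch" (bowtie) vertices: a vertex whose incident
# faces form more than one edge-connected fan gets one duplicate per extra
# fan. Face removal along box-shaped regions (osteotomy carving) can create
# such vertices at region corners.
.splitPinchVertices <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  vl <- mesh@vertexLabels
  hasVL <- length(vl) > 0
  inc <- split(rep(seq_len(nrow(f)), 3), as.vector(f))
  newRows <- list()
  for (vi in as.integer(names(inc))) {
    fs <- inc[[as.character(vi)]]
    if (length(fs) < 2) next
    # union-find fans: faces sharing an edge incident to vi
    parent <- seq_along(fs)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    others <- lapply(fs, function(fi) setdiff(f[fi, ], vi))
    for (i in seq_along(fs)) for (j in seq_len(i - 1)) {
      if (length(intersect(others[[i]], others[[j]]))) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
    roots <- vapply(seq_along(fs), find, 1L)
    comps <- unique(roots)
    if (length(comps) == 1) next
    for (ci in comps[-1]) {
      newRows[[length(newRows) + 1]] <- v[vi, ]
      nid <- nrow(v) + length(newRows)
      if (hasVL) vl <- c(vl, vl[vi])
      for (fi in fs[roots == ci]) f[fi, f[fi, ] == vi] <- nid
    }
  }
  if (!length(newRows)) return(mesh)
  triSurface(rbind(v, do.call(rbind, newRows)), f, vl, mesh@faceLabels)
}

# connected components over faces (shared-edge adjacency); returns integer
# component id per face
.faceComponents <- function(mesh) {
  me <- .meshEdges(mesh)
  he <- me$he; grp <- me$grp
  m <- nFaces(mesh)
  parent <- seq_len(m)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  firsts <- c(1L, which(diff(grp) != 0) + 1L)
  pairs <- which(me$cnt == 2)
  for (p in pairs) {
    i <- firsts[p]
    f1 <- he[i, 4]; f2 <- he[i + 1, 4]
    r1 <- find(f1); r2 <- find(f2)
    if (r1 != r2) parent[r1] <- r2
  }
  roots <- vapply(seq_len(m), find, 1L)
  match(roots, unique(roots))
}

#' Separate the inner and outer skull tables
#'
#' Given a skull shell that is closed except (optionally) at the base rim,
#' removes a thin band of faces along the base plane and splits the rest
#' into the two connected surfaces; the one farther from the cavity centroid
#' is the outer table.
#'
#' @param closedSkull a [TriSurface-class], closed except the base rim.
#' @param basePlane the nasion-tragion [Plane-class].
#' @param rimBand width of the rim band to discard (mm); default twice the
#'   mean edge length.
#' @return list with elements `inner` and `outer` ([TriSurface-class]).
#' @export
separateInnerOuter <- function(closedSkull, basePlane, rimBand = NULL) {
  if (is.null(rimBand)) {
    ar <- faceAreas(closedSkull)
    rimBand <- 2 * sqrt(mean(ar) * 4 / sqrt(3)) # ~2 mean edge lengths
  }
  d <- signedDistance(basePlane, closedSkull@vertices)
  cen <- .faceCentroids(closedSkull)
  dc <- signedDistance(basePlane, cen)
  keep <- dc > rimBand
  if (!any(keep)) stop("separation error: no faces above the rim band")
  sub <- triSurface(closedSkull@vertices,
                    closedSkull@faces[keep, , drop = FALSE],
                    closedSkull@vertexLabels,
                    if (length(closedSkull@faceLabels))
                      closedSkull@faceLabels[keep] else character(0))
  sub <- .dropUnusedVertices(sub@vertices, sub@faces, sub@vertexLabels,
                             sub@faceLabels)
  comp <- .faceComponents(sub)
  ncomp <- max(comp)
  if (ncomp != 2)
    stop(sprintf("separation error: expected 2 components, found %d", ncomp))
  ctr <- colMeans(closedSkull@vertices)
  res <- lapply(1:2, function(ci) {
    m <- triSurface(sub@vertices, sub@faces[comp == ci, , drop = FALSE],
                    sub@vertexLabels,
                    if (length(sub@faceLabels)) sub@faceLabels[comp == ci]
                    else character(0))
    .dropUnusedVertices(m@vertices, m@faces, m@vertexLabels, m@faceLabels)
  })
  md <- vapply(res, function(m)
    mean(sqrt(rowSums(sweep(m@vertices, 2, ctr)^2))), 1)
  list(inner = res[[which.min(md)]], outer = res[[which.max(md)]])
}
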