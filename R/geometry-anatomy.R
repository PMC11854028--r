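# Landmark-based anatomical construction: base plane, anatomical frame,
# suture planes, osteotomy carving.

#' Fit the nasion-tragion base plane
#'
#' The plane through the nasion and the two tragions is the anatomical
#' reference for every construction: models are cut along it, skull height
#' is measured from it, and the suture-plane angles are defined against it.
#' With landmarks given in a right-handed coordinate frame (left tragion on
#' the patient's left), the returned normal points toward the cranial
#' vertex.
#'
#' @param nasion,tragionLeft,tragionRight numeric(3) landmark positions (mm).
#' @return a [Plane-class] containing all three points.
#' @examples
#' fitBasePlane(c(0, 0, 0), c(-60, -90, 0), c(60, -90, 0)) # z = 0, normal +z
#' @export
fitBasePlane <- function(nasion, tragionLeft, tragionRight) {
  u <- tragionLeft - nasion
  w <- tragionRight - nasion
  n <- c(u[2] * w[3] - u[3] * w[2],
         u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  nn <- sqrt(sum(n^2))
  scale <- max(sqrt(sum(u^2)), sqrt(sum(w^2)))
  if (nn < 1e-9 * scale^2)
    stop("degenerate geometry: landmarks are collinear or coincident")
  plane(nasion, n / nn)
}

#' Build an anatomical frame from landmarks
#'
#' Derives the base plane, the antero-posterior extreme points A and P of the
#' base-plane section, the midline (symmetry) plane through segment AP, and
#' optionally the suture-plane feet B and L at the given AP fractions.
#'
#' @param nasion,tragionLeft,tragionRight numeric(3), required landmarks.
#' @param mesh optional [TriSurface-class] used to locate A and P; if
#'   omitted, `A` and `P` must be supplied.
#' @param bregma,lambdaPt optional numeric(3) cranial landmarks.
#' @param abFrac,lpFrac optional AP fractions placing B (from A) and L (from
#'   P).
#' @param A,P optional explicit section extremes.
#' @return an [AnatomicalFrame-class].
#' @export
anatomicalFrame <- function(nasion, tragionLeft, tragionRight, mesh = NULL,
                            bregma = NULL, lambdaPt = NULL,
                            abFrac = NULL, lpFrac = NULL,
                            A = NULL, P = NULL) {
  basePlane <- fitBasePlane(nasion, tragionLeft, tragionRight)
  if (is.null(A) || is.null(P)) {
    if (is.null(mesh)) stop("either a mesh or explicit A/P must be given")
    ap <- findAPPoints(mesh, basePlane, anterior = nasion)
    A <- ap$A; P <- ap$P
  }
  apHat <- .unit(P - A)
  latHat <- .unit(c(apHat[2] * basePlane@normal[3] - apHat[3] * basePlane@normal[2],
                    apHat[3] * basePlane@normal[1] - apHat[1] * basePlane@normal[3],
                    apHat[1] * basePlane@normal[2] - apHat[2] * basePlane@normal[1]))
  midline <- plane(A, latHat)
  B <- if (!is.null(abFrac)) A + abFrac * (P - A) else numeric(0)
  L <- if (!is.null(lpFrac)) A + (1 - lpFrac) * (P - A) else numeric(0)
  new("AnatomicalFrame", nasion = as.numeric(nasion),
      tragionLeft = as.numeric(tragionLeft),
      tragionRight = as.numeric(tragionRight),
      bregma = if (is.null(bregma)) numeric(0) else as.numeric(bregma),
      lambdaPt = if (is.null(lambdaPt)) numeric(0) else as.numeric(lambdaPt),
      basePlane = basePlane, midlinePlane = midline,
      A = as.numeric(A), P = as.numeric(P), B = B, L = L)
}

# in-frame axes helper
.frameAxes <- function(frame) {
  apHat <- .unit(frame@P - frame@A)
  up <- frame@basePlane@normal
  lat <- frame@midlinePlane@normal
  list(apHat = apHat, up = up, lat = lat, apLen = sqrt(sum((frame@P - frame@A)^2)))
}

#' Construct the coronal and lambdoid suture planes
#'
#' Both planes are perpendicular to the midline plane. The coronal plane
#' passes through `B = A + abFrac (P - A)` and is tilted so that its trace
#' in the midline plane makes the angle `alpha` with the ray B->A; the
#' lambdoid plane passes through `L = P - lpFrac (P - A)` with angle `beta`
#' against the ray L->P. At 90 degrees the planes are perpendicular to the
#' AP segment. Plane normals are oriented to point posteriorly.
#'
#' @param frame an [AnatomicalFrame-class].
#' @param alpha,beta plane angles in degrees (0, 180).
#' @param abFrac,lpFrac AP fractions; default to the feet stored in `frame`.
#' @return list with `coronal` and `lambdoid` [Plane-class] objects and the
#'   foot points `B` and `L`.
#' @export
suturePlanes <- function(frame, alpha, beta, abFrac = NULL, lpFrac = NULL) {
  if (alpha <= 0 || alpha >= 180 || beta <= 0 || beta >= 180)
    stop("angles must lie in (0, 180) degrees")
  ax <- .frameAxes(frame)
  if (is.null(abFrac)) {
    if (!length(frame@B)) stop("abFrac not given and frame has no B")
    B <- frame@B
    abFrac <- sum((B - frame@A) * ax$apHat) / ax$apLen
  } else B <- frame@A + abFrac * (frame@P - frame@A)
  if (is.null(lpFrac)) {
    if (!length(frame@L)) stop("lpFrac not given and frame has no L")
    L <- frame@L
    lpFrac <- sum((frame@P - L) * ax$apHat) / ax$apLen
  } else L <- frame@P - lpFrac * (frame@P - frame@A)
  if (abFrac <= 0 || lpFrac <= 0 || abFrac >= 1 - lpFrac)
    stop("configuration error: require 0 < abFrac < 1 - lpFrac < 1")
  a <- alpha * pi / 180
  b <- beta * pi / 180
  traceC <- cos(a) * (-ax$apHat) + sin(a) * ax$up  # cranial-going, angle at B->A
  traceL <- cos(b) * ax$apHat + sin(b) * ax$up     # cranial-going, angle at L->P
  nC <- .unit(c(traceC[2] * ax$lat[3] - traceC[3] * ax$lat[2],
                traceC[3] * ax$lat[1] - traceC[1] * ax$lat[3],
                traceC[1] * ax$lat[2] - traceC[2] * ax$lat[1]))
  nL <- .unit(c(traceL[2] * ax$lat[3] - traceL[3] * ax$lat[2],
                traceL[3] * ax$lat[1] - traceL[1] * ax$lat[3],
                traceL[1] * ax$lat[2] - traceL[2] * ax$lat[1]))
  if (sum(nC * ax$apHat) < 0) nC <- -nC
  if (sum(nL * ax$apHat) < 0) nL <- -nL
  list(coronal = plane(B, nC), lambdoid = plane(L, nL), B = B, L = L)
}

#' Carve parasagittal osteotomies and spring notches
#'
#' Carves two open cuts of the specified kerf width through the parietal
#' region, parallel to the midline at `lateralOffset`, running between the
#' anterior and posterior AP extents, and marks four notch vertex sets (an
#' anterior and a posterior notch on the lateral edge of each cut) where the
#' spring footplates seat. Faces outside a tube of roughly
#' kerf + 2 edge lengths around the cut lines are untouched.
#'
#' @param model a region-labeled [TriSurface-class] (see [buildSModel()]).
#' @param frame the [AnatomicalFrame-class] of the model.
#' @param spec an [OsteotomySpec-class].
#' @return list with `mesh` (carved [TriSurface-class], notch vertices
#'   labeled) and `notchSets` (named list of 4 integer vertex sets:
#'   anterior_left, anterior_right, posterior_left, posterior_right).
#' @export
carveOsteotomies <- function(model, frame, spec) {
  validObject(spec)
  if (!length(model@faceLabels)) stop("spec error: model must be region-labeled")
  ax <- .frameAxes(frame)
  edgeLen <- sqrt(mean(faceAreas(model)) * 4 / sqrt(3))
  apA <- spec@anteriorExtent * ax$apLen
  apP <- spec@posteriorExtent * ax$apLen
  k2 <- spec@kerf / 2

  # which lateral sign is the patient's right
  rightSign <- sign(sum((frame@tragionRight - frame@tragionLeft) * ax$lat))
  if (rightSign == 0) rightSign <- 1

  mesh <- model
  apOf <- function(p) sum((p - frame@A) * ax$apHat)
  ltOf <- function(p) sum((p - frame@A) * ax$lat)
  for (side in c(-1, 1)) {
    ctrOff <- side * spec@lateralOffset
    # the two kerf-edge planes, cut only along the slot's AP extent
    for (pl in list(
      plane(frame@A + (ctrOff - k2) * ax$lat, ax$lat),
      plane(frame@A + (ctrOff + k2) * ax$lat, ax$lat))) {
      win <- function(p) {
        a <- apOf(p)
        a > apA - 2 * edgeLen && a < apP + 2 * edgeLen
      }
      mesh <- .planeSplit(mesh, pl, "both", snapFrac = 0.05, window = win)
    }
    # the two end-cap planes, cut only across the kerf width
    for (pl in list(plane(frame@A + apA * ax$apHat, ax$apHat),
                    plane(frame@A + apP * ax$apHat, ax$apHat))) {
      win <- function(p) abs(ltOf(p) - ctrOff) < k2 + 1e-9
      mesh <- .planeSplit(mesh, pl, "both", snapFrac = 0.05, window = win)
    }
  }

  # remove the faces inside the two slots; per side, only the largest
  # edge-connected candidate component is removed, so stray fragments at
  # the box corners (left whole by snapping) do not punch extra holes
  cen <- .faceCentroids(mesh)
  lt <- drop(sweep(cen, 2, frame@A) %*% ax$lat)
  ap <- drop(sweep(cen, 2, frame@A) %*% ax$apHat)
  inSlot <- rep(FALSE, nFaces(mesh))
  for (side in c(-1, 1)) {
    cand <- which(abs(lt - side * spec@lateralOffset) < k2 - 1e-9 &
                    ap > apA + 1e-9 & ap < apP - 1e-9)
    if (!length(cand)) next
    sub <- triSurface(mesh@vertices, mesh@faces[cand, , drop = FALSE])
    comp <- .faceComponents(sub)
    big <- which.max(tabulate(comp))
    inSlot[cand[comp == big]] <- TRUE
  }
  if (!any(inSlot)) stop("spec error: osteotomy cuts do not intersect the model")
  if (!all(mesh@faceLabels[inSlot] == "parietal"))
    stop("spec error: cut extends outside the parietal region")
  keep <- !inSlot
  vl <- if (length(mesh@vertexLabels)) mesh@vertexLabels
        else rep("", nVertices(mesh))
  mesh <- .dropUnusedVertices(mesh@vertices, mesh@faces[keep, , drop = FALSE],
                              vl, mesh@faceLabels[keep])
  mesh <- .splitPinchVertices(mesh) # slot corners can pinch the boundary

  # box removal can leave small corner holes next to the slots; fill
  # everything except the base rim (lowest loop) and the two slots (the
  # largest remaining loops)
  lps <- boundaryLoops(mesh)
  if (length(lps) > 3) {
    hts <- vapply(lps, function(l)
      mean(signedDistance(frame@basePlane, mesh@vertices[l, , drop = FALSE])),
      1)
    rim <- which.min(hts)
    rest <- setdiff(seq_along(lps), rim)
    slots <- rest[order(vapply(lps[rest], length, 1L),
                        decreasing = TRUE)[1:2]]
    mesh <- .fillLoops(mesh, lps[setdiff(rest, slots)], label = "parietal")
  }

  # notch vertex sets on the lateral edge of each slot
  vlt <- drop(sweep(mesh@vertices, 2, frame@A) %*% ax$lat)
  vap <- drop(sweep(mesh@vertices, 2, frame@A) %*% ax$apHat)
  notchSets <- list()
  vl <- mesh@vertexLabels
  for (nf in seq_along(spec@notchFractions)) {
    fr <- spec@notchFractions[nf]
    apN <- apA + fr * (apP - apA)
    for (side in c(-1, 1)) {
      lateralEdge <- side * (spec@lateralOffset + k2)
      radius <- 1.5 * edgeLen
      repeat {
        set <- which(abs(vlt - lateralEdge) < 1e-3 & abs(vap - apN) <= radius)
        if (length(set) || radius > 6 * edgeLen) break
        radius <- radius * 1.5
      }
      if (!length(set))
        stop("spec error: empty notch set (cut too short or mesh too coarse)")
      nm <- paste0(if (nf == 1) "anterior" else "posterior", "_",
                   if (side == rightSign) "right" else "left")
      notchSets[[nm]] <- set
      vl[set] <- paste0("notch_", nm)
    }
  }
  notchSets <- notchSets[c("anterior_left", "anterior_right",
                           "posterior_left", "posterior_right")]
  # a vertex can fall inside two notch windows on coarse meshes; keep it in
  # the nearest one only
  all4 <- unlist(notchSets)
  if (anyDuplicated(all4)) {
    for (d in unique(all4[duplicated(all4)])) {
      inSets <- names(which(vapply(notchSets, function(s) d %in% s, TRUE)))
      keepIn <- inSets[which.min(vapply(inSets, function(nm) {
        fr <- if (grepl("anterior", nm)) spec@notchFractions[1]
              else spec@notchFractions[2]
        abs(vap[d] - (apA + fr * (apP - apA)))
      }, 1))]
      for (nm in setdiff(inSets, keepIn))
        notchSets[[nm]] <- setdiff(notchSets[[nm]], d)
    }
  }
  mesh@vertexLabels <- vl
  list(mesh = mesh, notchSets = notchSets)
}
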