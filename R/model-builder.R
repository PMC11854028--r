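# Assembly of simulation-ready skull models: the S model built from a head
# surface with population-averaged parameters, and ingestion of
# pre-segmented CT-like skull meshes.

# Label shell faces into the five regions using the two suture planes.
# The shell is first split geometrically along the band-edge planes
# (suture plane offset by +/- half the suture width), so each band is an
# exact strip rather than a row of whole faces; labels then follow the face
# centroid.
.labelRegions <- function(mesh, coronal, lambdoid, sutureWidth) {
  w2 <- sutureWidth / 2
  for (pl in list(coronal, lambdoid))
    for (s in c(-1, 1))
      mesh <- splitByPlane(mesh,
                           plane(pl@point + s * w2 * pl@normal, pl@normal),
                           snapFrac = 0.1)
  cen <- .faceCentroids(mesh)
  dC <- signedDistance(coronal, cen)
  dL <- signedDistance(lambdoid, cen)
  labels <- rep("parietal", nrow(cen))
  labels[dC < -w2] <- "frontal"
  labels[dL > w2] <- "occipital"
  labels[abs(dC) <= w2] <- "coronal_suture"
  labels[abs(dL) <= w2] <- "lambdoid_suture"
  regs <- c("frontal", "coronal_suture", "parietal", "lambdoid_suture",
            "occipital")
  missing <- setdiff(regs, unique(labels))
  if (length(missing))
    stop(sprintf("configuration error: empty region(s): %s",
                 paste(missing, collapse = ", ")))
  mesh@faceLabels <- labels
  mesh
}

#' Build an S model from a head surface scan
#'
#' Implements the full surface-scan pipeline: cut the head surface at the
#' nasion-tragion plane, offset it inward by the population-average scalp
#' thickness to estimate the outer skull table, locate the AP extremes,
#' construct the coronal and lambdoid suture planes from the
#' population-average angles and foot ratios, split the shell into the five
#' regions with suture bands of the nominal width, and carve the
#' parasagittal osteotomies and spring notches. The model's homogeneous
#' shell thickness is the population-average skull thickness.
#'
#' Bregma and lambda are *not* required: suture placement relies entirely on
#' the population averages, which is the point of the radiation-free
#' construction.
#'
#' @param headSurface a closed head [TriSurface-class].
#' @param landmarks named list with `nasion`, `tragion_left`,
#'   `tragion_right` (numeric(3), mm).
#' @param pop a [PopulationParams-class].
#' @param spec an [OsteotomySpec-class].
#' @return a [SkullModel-class] with provenance "S".
#' @examples
#' ph <- generateHead(phantomSpec(meshResolution = 6))
#' mod <- buildSModel(ph$mesh, ph$landmarks, populationParams(),
#'                    osteotomySpec())
#' mod
#' @export
buildSModel <- function(headSurface, landmarks, pop = populationParams(),
                        spec = osteotomySpec()) {
  stage <- function(nm, expr) tryCatch(expr, error = function(e)
    stop(sprintf("buildSModel stage '%s': %s", nm, conditionMessage(e)),
         call. = FALSE))
  basePlane <- stage("base_plane",
    fitBasePlane(landmarks$nasion, landmarks$tragion_left,
                 landmarks$tragion_right))
  cut <- stage("base_cut", cutByPlane(headSurface, basePlane, "positive"))
  skull <- stage("offset",
    if (pop@skinThickness > 0) offsetInward(cut, pop@skinThickness) else cut)
  frame <- stage("frame",
    anatomicalFrame(landmarks$nasion, landmarks$tragion_left,
                    landmarks$tragion_right, mesh = skull,
                    bregma = landmarks$bregma, lambdaPt = landmarks$lambda,
                    abFrac = pop@suture@abFrac, lpFrac = pop@suture@lpFrac))
  sp <- stage("suture_planes",
    suturePlanes(frame, pop@suture@alpha, pop@suture@beta))
  labeled <- stage("region_split",
    .labelRegions(skull, sp$coronal, sp$lambdoid, pop@sutureWidth))
  carved <- stage("osteotomies", carveOsteotomies(labeled, frame, spec))
  model <- new("SkullModel", shell = carved$mesh,
               thickness = pop@skullThickness, frame = frame,
               notchSets = carved$notchSets, provenance = "S",
               springs = list(), sutureWidth = pop@sutureWidth,
               coronalPlane = sp$coronal, lambdoidPlane = sp$lambdoid)
  ci <- shapeMetrics(model@shell, frame)@ci
  if (ci < 0.4 || ci > 1.2)
    warning(sprintf("sanity: cephalic index %.3f outside (0.4, 1.2)", ci))
  model
}

#' Ingest a pre-segmented CT-like skull mesh
#'
#' Applies a uniform growth rescale about the centroid, then labels regions:
#' if bregma and lambda are supplied, the suture planes are *measured*
#' (each plane passes through its cranial landmark and the
#' population-fraction foot on AP, perpendicular to the midline plane);
#' otherwise the population-average planes are used as in [buildSModel()].
#'
#' @param skullOuter an already-cut outer skull [TriSurface-class].
#' @param landmarks named list with nasion/tragions and optionally
#'   bregma/lambda.
#' @param scaleFactor uniform scale (>0) accounting for growth between scan
#'   and surgery; supplied by the user.
#' @param pop a [PopulationParams-class] (fallback suture geometry and
#'   thickness).
#' @param spec an [OsteotomySpec-class].
#' @return a [SkullModel-class] with provenance "CT".
#' @export
ingestCTModel <- function(skullOuter, landmarks, scaleFactor = 1,
                          pop = populationParams(), spec = osteotomySpec()) {
  if (scaleFactor <= 0) stop("input error: scaleFactor must be > 0")
  mesh <- skullOuter
  if (scaleFactor != 1) {
    ctr <- colMeans(mesh@vertices)
    mesh@vertices <- sweep(sweep(mesh@vertices, 2, ctr) * scaleFactor, 2, -ctr)
    landmarks <- lapply(landmarks, function(p)
      if (is.null(p)) NULL else ctr + scaleFactor * (p - ctr))
  }
  basePlane <- fitBasePlane(landmarks$nasion, landmarks$tragion_left,
                            landmarks$tragion_right)
  frame <- anatomicalFrame(landmarks$nasion, landmarks$tragion_left,
                           landmarks$tragion_right, mesh = mesh,
                           bregma = landmarks$bregma,
                           lambdaPt = landmarks$lambda,
                           abFrac = pop@suture@abFrac,
                           lpFrac = pop@suture@lpFrac)
  measured <- length(frame@bregma) == 3 && length(frame@lambdaPt) == 3
  if (measured) {
    geom <- measureSutureGeometry(frame)
    sp <- suturePlanes(frame, geom@alpha, geom@beta)
  } else {
    sp <- suturePlanes(frame, pop@suture@alpha, pop@suture@beta)
  }
  labeled <- .labelRegions(mesh, sp$coronal, sp$lambdoid, pop@sutureWidth)
  carved <- carveOsteotomies(labeled, frame, spec)
  new("SkullModel", shell = carved$mesh, thickness = pop@skullThickness,
      frame = frame, notchSets = carved$notchSets, provenance = "CT",
      springs = list(), sutureWidth = pop@sutureWidth,
      coronalPlane = sp$coronal, lambdoidPlane = sp$lambdoid)
}

#' Default spring distractor table
#'
#' The three clinical spring models share the same geometry (60 mm nominal
#' fully-open length) and differ in wire diameter (1.0, 1.2, 1.4 mm), hence
#' stiffness. The stiffness values here are package defaults scaled as the
#' fourth power of wire diameter; they are configuration, not measured
#' device constants, and should be replaced with calibrated values when
#' available.
#'
#' @return data.frame with columns `model`, `stiffness` (N/mm),
#'   `freeLength` (mm).
#' @export
defaultSpringTable <- function() {
  data.frame(model = c("S10", "S12", "S14"),
             stiffness = c(0.25, 0.25 * 1.2^4, 0.25 * 1.4^4),
             freeLength = 60)
}

#' Attach anterior and posterior springs to a model
#'
#' The anterior spring connects the anterior notch pair across the midline
#' (left to right), the posterior spring the posterior pair; each spring
#' attaches at the vertex of its notch set nearest the set centroid.
#'
#' @param model a [SkullModel-class] with 4 notch sets.
#' @param springModels character(2): anterior and posterior spring model IDs
#'   from `springTable$model`.
#' @param springTable data.frame as [defaultSpringTable()].
#' @return the model with two [SpringElement-class] objects in `@springs`.
#' @examples
#' ph <- generateHead(phantomSpec(meshResolution = 6))
#' mod <- buildSModel(ph$mesh, ph$landmarks)
#' mod <- attachSprings(mod, c("S12", "S10"))
#' @export
attachSprings <- function(model, springModels = c("S12", "S12"),
                          springTable = defaultSpringTable()) {
  if (length(springModels) != 2) stop("config error: need 2 spring models")
  if (!all(springModels %in% springTable$model))
    stop(sprintf("config error: unknown spring ID(s): %s",
                 paste(setdiff(springModels, springTable$model),
                       collapse = ", ")))
  if (length(model@notchSets) != 4 ||
      any(!vapply(model@notchSets, length, 1L)))
    stop("config error: model must carry 4 non-empty notch sets")
  centroidNode <- function(set) {
    pts <- model@shell@vertices[set, , drop = FALSE]
    ctr <- colMeans(pts)
    set[which.min(rowSums(sweep(pts, 2, ctr)^2))]
  }
  springs <- lapply(1:2, function(i) {
    pos <- if (i == 1) "anterior" else "posterior"
    row <- springTable[springTable$model == springModels[i], ][1, ]
    springElement(row$model, row$stiffness, row$freeLength,
                  nodeA = centroidNode(model@notchSets[[paste0(pos, "_left")]]),
                  nodeB = centroidNode(model@notchSets[[paste0(pos, "_right")]]))
  })
  names(springs) <- c("anterior", "posterior")
  model@springs <- springs
  model
}
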