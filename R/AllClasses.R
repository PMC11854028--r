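# S4 classes for the whole toolkit. All lengths are millimetres, all angles
# are degrees at the API surface (radians are used internally only).

#' TriSurface: an indexed triangle mesh
#'
#' Vertices are stored as an `n x 3` numeric matrix (mm), faces as an
#' `m x 3` integer matrix of 1-based vertex indices, oriented
#' counter-clockwise seen from outside. Optional per-vertex and per-face
#' character labels carry anatomical region tags ("frontal",
#' "coronal_suture", ...) and notch markers through the pipeline.
#'
#' @slot vertices numeric matrix, one 3D point per row (mm).
#' @slot faces integer matrix of vertex index triples.
#' @slot vertexLabels character vector of length `nrow(vertices)` or 0.
#' @slot faceLabels character vector of length `nrow(faces)` or 0.
#' @export
setClass("TriSurface",
  representation(vertices = "matrix", faces = "matrix",
                 vertexLabels = "character", faceLabels = "character"),
  prototype(vertexLabels = character(0), faceLabels = character(0)))

setValidity("TriSurface", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3) return("vertices must have 3 columns")
  if (nrow(f) > 0 && ncol(f) != 3) return("faces must have 3 columns")
  if (!is.numeric(v)) return("vertices must be numeric")
  if (nrow(f) > 0) {
    if (!is.numeric(f)) return("faces must be integer-valued")
    if (min(f) < 1 || max(f) > nrow(v)) return("face index out of range")
    ar <- faceAreas(object)
    if (any(ar <= 1e-12))
      return(sprintf("%d degenerate (zero-area) faces", sum(ar <= 1e-12)))
  }
  if (length(object@vertexLabels) && length(object@vertexLabels) != nrow(v))
    return("vertexLabels length mismatch")
  if (length(object@faceLabels) && length(object@faceLabels) != nrow(f))
    return("faceLabels length mismatch")
  TRUE
})

#' Construct a TriSurface
#'
#' @param vertices numeric `n x 3` matrix of points (mm).
#' @param faces integer `m x 3` matrix of 1-based vertex indices.
#' @param vertexLabels,faceLabels optional character label vectors.
#' @return A [TriSurface-class] object.
#' @examples
#' s <- triSurface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                 matrix(c(1L, 2L, 3L), 1))
#' nFaces(s)
#' @export
triSurface <- function(vertices, faces,
                       vertexLabels = character(0),
                       faceLabels = character(0)) {
  storage.mode(faces) <- "integer"
  vertices <- as.matrix(vertices)
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  new("TriSurface", vertices = vertices, faces = faces,
      vertexLabels = as.character(vertexLabels),
      faceLabels = as.character(faceLabels))
}

#' Plane: a point and a unit normal
#'
#' @slot point numeric(3), a point on the plane (mm).
#' @slot normal numeric(3), unit normal.
#' @export
setClass("Plane", representation(point = "numeric", normal = "numeric"))

setValidity("Plane", function(object) {
  if (length(object@point) != 3 || length(object@normal) != 3)
    return("point and normal must be length-3")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    return("normal must be unit length (|n| = 1 +/- 1e-9)")
  TRUE
})

#' Construct a Plane
#'
#' @param point numeric(3), a point on the plane (mm).
#' @param normal numeric(3); normalised internally unless degenerate.
#' @return A [Plane-class] object.
#' @export
plane <- function(point, normal) {
  nn <- sqrt(sum(normal^2))
  if (nn < 1e-12) stop("degenerate plane normal")
  new("Plane", point = as.numeric(point), normal = as.numeric(normal) / nn)
}

#' AnatomicalFrame: landmark-derived coordinate scaffold
#'
#' Holds the anatomical landmarks and the planes and points derived from
#' them: the nasion-tragion base plane, the midline (symmetry) plane through
#' the antero-posterior (AP) segment, the extreme section points A and P, and
#' the suture-plane feet B (coronal) and L (lambdoid) on segment AP.
#' Optional landmarks (bregma, lambda, B, L) are stored as `numeric(0)` when
#' absent.
#'
#' @slot nasion,tragionLeft,tragionRight numeric(3) landmark positions (mm).
#' @slot bregma,lambdaPt numeric(3) or numeric(0).
#' @slot basePlane,midlinePlane [Plane-class] objects.
#' @slot A,P numeric(3): most anterior / most posterior points on the base
#'   plane section.
#' @slot B,L numeric(3) or numeric(0): suture-plane feet on segment AP.
#' @export
setClass("AnatomicalFrame",
  representation(nasion = "numeric", tragionLeft = "numeric",
                 tragionRight = "numeric", bregma = "numeric",
                 lambdaPt = "numeric", basePlane = "Plane",
                 midlinePlane = "Plane", A = "numeric", P = "numeric",
                 B = "numeric", L = "numeric"))

setValidity("AnatomicalFrame", function(object) {
  tol <- 1e-6
  for (nm in c("A", "P"))
    if (abs(signedDistance(object@basePlane, rbind(slot(object, nm)))) > 1e-3)
      return(sprintf("%s does not lie on the base plane", nm))
  ap <- object@P - object@A
  lap <- sqrt(sum(ap^2))
  if (lap < tol) return("A and P coincide")
  for (nm in c("B", "L")) {
    p <- slot(object, nm)
    if (length(p) == 3) {
      tpar <- sum((p - object@A) * ap) / lap^2
      perp <- sqrt(sum((p - (object@A + tpar * ap))^2))
      if (tpar < -1e-9 || tpar > 1 + 1e-9 || perp > 1e-3)
        return(sprintf("%s does not lie on segment AP", nm))
    }
  }
  if (abs(sum(object@midlinePlane@normal * object@basePlane@normal)) > 1e-6)
    return("midline plane normal not perpendicular to base plane normal")
  TRUE
})

#' SutureGeometry: suture-plane angles and foot ratios
#'
#' The coronal angle alpha is the point angle A-B-Bregma, the lambdoid angle
#' beta is P-L-Lambda; abFrac = |AB|/|AP| and lpFrac = |LP|/|AP| locate the
#' plane feet on the AP segment.
#'
#' @slot alpha,beta numeric(1), degrees in (0, 180).
#' @slot abFrac,lpFrac numeric(1), ratios in (0, 1).
#' @export
setClass("SutureGeometry",
  representation(alpha = "numeric", beta = "numeric",
                 abFrac = "numeric", lpFrac = "numeric"))

setValidity("SutureGeometry", function(object) {
  if (object@alpha <= 0 || object@alpha >= 180) return("alpha outside (0, 180)")
  if (object@beta <= 0 || object@beta >= 180) return("beta outside (0, 180)")
  if (object@abFrac <= 0 || object@abFrac >= 1) return("abFrac outside (0, 1)")
  if (object@lpFrac <= 0 || object@lpFrac >= 1) return("lpFrac outside (0, 1)")
  TRUE
})

#' Construct a SutureGeometry
#'
#' Defaults are the population averages reported for spring-assisted
#' cranioplasty cohorts: coronal angle 83 degrees, lambdoid angle 68 degrees.
#' The foot ratios default to 0.30 (AB/AP) and 0.25 (LP/AP).
#'
#' @param alpha,beta suture-plane angles in degrees.
#' @param abFrac,lpFrac suture-foot position ratios along AP.
#' @return A [SutureGeometry-class] object.
#' @export
sutureGeometry <- function(alpha = 83, beta = 68, abFrac = 0.30, lpFrac = 0.25) {
  new("SutureGeometry", alpha = alpha, beta = beta,
      abFrac = abFrac, lpFrac = lpFrac)
}

#' PopulationParams: averaged tissue and suture parameters
#'
#' @slot skinThickness numeric(1), mm (population default 2.8).
#' @slot skullThickness numeric(1), mm (population default 2.5).
#' @slot suture [SutureGeometry-class].
#' @slot sutureWidth numeric(1), mm (default 2).
#' @slot sds named numeric vector of standard deviations (may be empty).
#' @export
setClass("PopulationParams",
  representation(skinThickness = "numeric", skullThickness = "numeric",
                 suture = "SutureGeometry", sutureWidth = "numeric",
                 sds = "numeric"),
  prototype(sds = numeric(0)))

setValidity("PopulationParams", function(object) {
  if (object@skinThickness <= 0) return("skinThickness must be positive")
  if (object@skullThickness <= 0) return("skullThickness must be positive")
  if (object@sutureWidth <= 0) return("sutureWidth must be positive")
  TRUE
})

#' Construct PopulationParams
#'
#' Defaults are the published population averages for infants treated for
#' scaphocephaly: soft-tissue (scalp) thickness 2.8 mm, skull thickness
#' 2.5 mm, coronal angle 83 degrees, lambdoid angle 68 degrees, and sutures
#' assumed 2 mm wide.
#'
#' @param skinThickness,skullThickness mm.
#' @param suture a [SutureGeometry-class].
#' @param sutureWidth mm.
#' @param sds optional named numeric of standard deviations.
#' @return A [PopulationParams-class] object.
#' @export
populationParams <- function(skinThickness = 2.8, skullThickness = 2.5,
                             suture = sutureGeometry(), sutureWidth = 2,
                             sds = numeric(0)) {
  new("PopulationParams", skinThickness = skinThickness,
      skullThickness = skullThickness, suture = suture,
      sutureWidth = sutureWidth, sds = sds)
}

#' ThicknessMap: per-vertex surface-distance thickness
#'
#' @slot distances numeric vector of per-vertex nearest-surface distances (mm)
#'   for the vertices above the crop plane.
#' @slot mean,sd numeric(1) summary of `distances`.
#' @slot cropPlane [Plane-class] used to exclude skull base and orbits.
#' @export
setClass("ThicknessMap",
  representation(distances = "numeric", mean = "numeric", sd = "numeric",
                 cropPlane = "Plane"))

setValidity("ThicknessMap", function(object) {
  if (any(object@distances < 0)) return("distances must be >= 0")
  if (abs(object@mean - mean(object@distances)) > 1e-9 * (1 + object@mean))
    return("mean inconsistent with distances")
  TRUE
})

#' ShapeMetrics: BPD, OFD and cephalic index
#'
#' @slot bpd numeric(1), biparietal (maximum lateral) dimension, mm.
#' @slot ofd numeric(1), occipitofrontal (maximum AP) dimension, mm.
#' @slot ci numeric(1), cephalic index = bpd / ofd.
#' @export
setClass("ShapeMetrics",
  representation(bpd = "numeric", ofd = "numeric", ci = "numeric"))

setValidity("ShapeMetrics", function(object) {
  if (object@bpd <= 0 || object@ofd <= 0) return("BPD and OFD must be positive")
  if (abs(object@ci - object@bpd / object@ofd) > 1e-9)
    return("ci must equal bpd/ofd")
  TRUE
})

#' OsteotomySpec: parasagittal cut and notch geometry
#'
#' The published surgical figures show two bony cuts parallel to the fused
#' sagittal suture with notches for the spring footplates, but do not
#' dimension them; these defaults are package choices, surfaced in the run
#' configuration so they can be set per case.
#'
#' @slot lateralOffset numeric(1), mm from the midline to each cut (default 25).
#' @slot kerf numeric(1), cut width in mm (default 1).
#' @slot anteriorExtent,posteriorExtent numeric(1), fractions of AP between
#'   which the cuts run (defaults 0.34 and 0.76, clear of the tilted suture-plane traces).
#' @slot notchFractions numeric(2), anterior/posterior notch positions as
#'   fractions of the cut length (defaults 0.25 and 0.75).
#' @export
setClass("OsteotomySpec",
  representation(lateralOffset = "numeric", kerf = "numeric",
                 anteriorExtent = "numeric", posteriorExtent = "numeric",
                 notchFractions = "numeric"))

setValidity("OsteotomySpec", function(object) {
  if (object@kerf <= 0) return("kerf must be > 0")
  if (object@lateralOffset <= 0) return("lateralOffset must be > 0")
  fr <- c(object@anteriorExtent, object@posteriorExtent, object@notchFractions)
  if (any(fr <= 0) || any(fr >= 1)) return("fractions must lie in (0, 1)")
  if (object@anteriorExtent >= object@posteriorExtent)
    return("anteriorExtent must be < posteriorExtent")
  if (length(object@notchFractions) != 2) return("notchFractions must be length 2")
  TRUE
})

#' Construct an OsteotomySpec
#' @param lateralOffset,kerf mm.
#' @param anteriorExtent,posteriorExtent fractions of AP.
#' @param notchFractions numeric(2) fractions of the cut length.
#' @return An [OsteotomySpec-class] object.
#' @export
osteotomySpec <- function(lateralOffset = 25, kerf = 1,
                          anteriorExtent = 0.34, posteriorExtent = 0.76,
                          notchFractions = c(0.25, 0.75)) {
  new("OsteotomySpec", lateralOffset = lateralOffset, kerf = kerf,
      anteriorExtent = anteriorExtent, posteriorExtent = posteriorExtent,
      notchFractions = notchFractions)
}

#' Material: elastic and viscoelastic (Prony) shell material
#'
#' Viscoelasticity is a Prony relaxation series on the modulus,
#' `g(t) = 1 - sum_i g_i (1 - exp(-t / tau_i))`, so the long-term modulus is
#' `E (1 - sum g_i)`.
#'
#' @slot youngsModulus numeric(1), MPa.
#' @slot poisson numeric(1) in `[0, 0.5)`.
#' @slot pronyG numeric vector of relaxation weights (may be empty).
#' @slot pronyTau numeric vector of relaxation times, s.
#' @export
setClass("Material",
  representation(youngsModulus = "numeric", poisson = "numeric",
                 pronyG = "numeric", pronyTau = "numeric"),
  prototype(pronyG = numeric(0), pronyTau = numeric(0)))

setValidity("Material", function(object) {
  if (object@youngsModulus <= 0) return("youngsModulus must be > 0")
  if (object@poisson < 0 || object@poisson >= 0.5)
    return("poisson must be in [0, 0.5)")
  if (length(object@pronyG) != length(object@pronyTau))
    return("pronyG and pronyTau lengths differ")
  if (sum(object@pronyG) >= 1) return("sum of pronyG must be < 1")
  if (any(object@pronyG < 0)) return("pronyG must be >= 0")
  if (any(object@pronyTau <= 0)) return("pronyTau must be > 0")
  TRUE
})

#' Construct a Material
#' @param youngsModulus MPa.
#' @param poisson Poisson ratio.
#' @param pronyG,pronyTau Prony series weights and times (s).
#' @return A [Material-class] object.
#' @export
material <- function(youngsModulus, poisson,
                     pronyG = numeric(0), pronyTau = numeric(0)) {
  new("Material", youngsModulus = youngsModulus, poisson = poisson,
      pronyG = pronyG, pronyTau = pronyTau)
}

#' SpringElement: a linear push-only spring distractor
#'
#' Force is `stiffness * (freeLength - opening)`, clamped at zero (the
#' distractor pushes only, never pulls). The nominal fully-open length of
#' all clinical models (S10/S12/S14) is 60 mm.
#'
#' @slot modelId character(1), one of "S10", "S12", "S14".
#' @slot stiffness numeric(1), N/mm.
#' @slot freeLength numeric(1), mm.
#' @slot nodeA,nodeB integer(1), attachment vertex indices.
#' @export
setClass("SpringElement",
  representation(modelId = "character", stiffness = "numeric",
                 freeLength = "numeric", nodeA = "integer", nodeB = "integer"))

setValidity("SpringElement", function(object) {
  if (object@stiffness <= 0) return("stiffness must be > 0")
  if (object@freeLength <= 0) return("freeLength must be > 0")
  TRUE
})

#' Construct a SpringElement
#' @param modelId spring model label.
#' @param stiffness N/mm.
#' @param freeLength mm (nominal 60).
#' @param nodeA,nodeB attachment vertex indices (may be NA before attachment).
#' @return A [SpringElement-class] object.
#' @export
springElement <- function(modelId, stiffness, freeLength = 60,
                          nodeA = NA_integer_, nodeB = NA_integer_) {
  new("SpringElement", modelId = as.character(modelId), stiffness = stiffness,
      freeLength = freeLength, nodeA = as.integer(nodeA),
      nodeB = as.integer(nodeB))
}

#' SkullModel: a labeled, simulation-ready skull shell
#'
#' @slot shell [TriSurface-class] with face labels in frontal /
#'   coronal_suture / parietal / lambdoid_suture / occipital.
#' @slot thickness numeric(1), homogeneous shell thickness (mm).
#' @slot frame [AnatomicalFrame-class].
#' @slot notchSets named list of 4 integer vectex-index vectors
#'   (anterior_left, anterior_right, posterior_left, posterior_right).
#' @slot provenance character(1), "S" (surface-scan) or "CT".
#' @slot springs list of [SpringElement-class] (empty before
#'   [attachSprings()]).
#' @slot sutureWidth numeric(1), mm, the nominal suture band width.
#' @export
setClass("SkullModel",
  representation(shell = "TriSurface", thickness = "numeric",
                 frame = "AnatomicalFrame", notchSets = "list",
                 provenance = "character", springs = "list",
                 sutureWidth = "numeric", coronalPlane = "Plane",
                 lambdoidPlane = "Plane"),
  prototype(springs = list(), sutureWidth = 2))

setValidity("SkullModel", function(object) {
  regs <- c("frontal", "coronal_suture", "parietal", "lambdoid_suture",
            "occipital")
  fl <- object@shell@faceLabels
  if (!length(fl)) return("shell must carry face labels")
  if (!all(fl %in% regs)) return("unknown face region label")
  if (!all(regs %in% fl)) return("one or more regions are empty")
  if (length(object@notchSets)) {
    if (length(object@notchSets) != 4) return("notchSets must have 4 entries")
    if (any(!vapply(object@notchSets, length, 1L)))
      return("empty notch set")
    all4 <- unlist(object@notchSets)
    if (anyDuplicated(all4)) return("notch sets overlap")
  }
  if (!object@provenance %in% c("S", "CT"))
    return("provenance must be 'S' or 'CT'")
  if (object@thickness <= 0) return("thickness must be > 0")
  TRUE
})

#' FESystem: assembled shell finite-element system
#'
#' Produced by [femAssemble()] (from a [SkullModel-class]) or [femSystem()]
#' (from a raw mesh, for benchmarks). Vertices beyond `nReal` are ghost
#' vertices implementing clamped-edge rotational restraint.
#'
#' @slot X0 numeric matrix, rest coordinates including ghost vertices.
#' @slot nReal integer(1), number of real mesh vertices.
#' @slot faces integer matrix.
#' @slot thickness numeric(1), mm.
#' @slot fixed logical vector over all vertices (ghosts always TRUE).
#' @slot faceGroup integer vector mapping faces to material groups.
#' @slot groups character vector of group names.
#' @slot materials list of [Material-class], one per group.
#' @slot faceMu,faceLam numeric per-face plane-stress Lame parameters (MPa).
#' @slot hinges integer matrix (p0, p1, p2, p3) per bending hinge.
#' @slot hingeK numeric per-hinge bending stiffness (N mm).
#' @slot hingeTheta0 numeric per-hinge rest dihedral (radians).
#' @slot hingeGroup integer per-hinge material group.
#' @export
setClass("FESystem",
  representation(X0 = "matrix", nReal = "integer", faces = "matrix",
                 thickness = "numeric", fixed = "logical",
                 faceGroup = "integer", groups = "character",
                 materials = "list", faceMu = "numeric", faceLam = "numeric",
                 hinges = "matrix", hingeK = "numeric",
                 hingeTheta0 = "numeric", hingeGroup = "integer"))

#' ExpansionSolution: displacement and opening history
#'
#' @slot timePoints numeric vector of solved times (s).
#' @slot openings numeric matrix, one row per time point, one column per
#'   spring (mm).
#' @slot displacements list with named entries PREOP/POSTOP/FU of `n x 3`
#'   displacement matrices over real vertices (mm).
#' @slot deformedMeshes list of [TriSurface-class] at PREOP/POSTOP/FU.
#' @slot springs list of [SpringElement-class] used.
#' @slot diagnostics list: residuals, force balance, spring work, strain
#'   energy, convergence flags.
#' @export
setClass("ExpansionSolution",
  representation(timePoints = "numeric", openings = "matrix",
                 displacements = "list", deformedMeshes = "list",
                 springs = "list", diagnostics = "list"))

setValidity("ExpansionSolution", function(object) {
  if (nrow(object@openings) != length(object@timePoints))
    return("openings rows must match timePoints")
  fl <- vapply(object@springs, function(s) s@freeLength, 1)
  if (any(sweep(object@openings, 2, fl + 1e-6) > 0))
    return("openings exceed spring free length")
  TRUE
})

#' PhantomSpec: parameters of a synthetic scaphocephalic head phantom
#'
#' The default phantom is a moderately scaphocephalic infant head:
#' OFD 125 mm, BPD 96 mm (cephalic index 0.768), height 80 mm above the
#' nasion-tragion plane, with the published population-average tissue and
#' suture parameters.
#'
#' @slot ofd,bpd,height numeric(1), mm.
#' @slot skinThickness,skullThickness numeric(1), mm.
#' @slot suture [SutureGeometry-class].
#' @slot meshResolution numeric(1), target edge length in mm.
#' @slot seed integer(1), jitter seed.
#' @slot jitter numeric(1), sd of optional Gaussian vertex jitter (mm).
#' @slot squareness numeric(2), superellipsoid exponents (vertical,
#'   horizontal).
#' @export
setClass("PhantomSpec",
  representation(ofd = "numeric", bpd = "numeric", height = "numeric",
                 skinThickness = "numeric", skullThickness = "numeric",
                 suture = "SutureGeometry", meshResolution = "numeric",
                 seed = "integer", jitter = "numeric", squareness = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (object@bpd >= object@ofd)
    return("phantom must be scaphocephalic: bpd < ofd")
  if (any(c(object@ofd, object@bpd, object@height, object@skinThickness,
            object@skullThickness, object@meshResolution) <= 0))
    return("all lengths must be positive")
  if (object@jitter < 0) return("jitter must be >= 0")
  TRUE
})

#' Construct a PhantomSpec
#' @param ofd,bpd,height overall extents above the base plane, mm.
#' @param skinThickness,skullThickness layer thicknesses, mm.
#' @param suture a [SutureGeometry-class].
#' @param meshResolution target edge length, mm.
#' @param seed integer jitter seed.
#' @param jitter sd of Gaussian vertex jitter, mm (0 = none).
#' @param squareness superellipsoid exponents (vertical, horizontal).
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(ofd = 125, bpd = 96, height = 80,
                        skinThickness = 2.8, skullThickness = 2.5,
                        suture = sutureGeometry(), meshResolution = 3,
                        seed = 1L, jitter = 0, squareness = c(0.9, 0.95)) {
  new("PhantomSpec", ofd = ofd, bpd = bpd, height = height,
      skinThickness = skinThickness, skullThickness = skullThickness,
      suture = suture, meshResolution = meshResolution,
      seed = as.integer(seed), jitter = jitter, squareness = squareness)
}
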