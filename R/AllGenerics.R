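# Generics, accessors and show methods.

#' @rdname TriSurface-class
#' @param x,object a [TriSurface-class].
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname TriSurface-class
#' @export
setMethod("vertices", "TriSurface", function(x) x@vertices)

#' @rdname TriSurface-class
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname TriSurface-class
#' @export
setMethod("faces", "TriSurface", function(x) x@faces)

#' @rdname TriSurface-class
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname TriSurface-class
#' @export
setMethod("nVertices", "TriSurface", function(x) nrow(x@vertices))

#' @rdname TriSurface-class
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))
#' @rdname TriSurface-class
#' @export
setMethod("nFaces", "TriSurface", function(x) nrow(x@faces))

#' @rdname TriSurface-class
#' @export
setGeneric("faceLabels", function(x) standardGeneric("faceLabels"))
#' @rdname TriSurface-class
#' @export
setMethod("faceLabels", "TriSurface", function(x) x@faceLabels)

#' @rdname TriSurface-class
#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))
#' @rdname TriSurface-class
#' @export
setMethod("vertexLabels", "TriSurface", function(x) x@vertexLabels)

setMethod("show", "TriSurface", function(object) {
  cat(sprintf("TriSurface: %d vertices, %d faces", nVertices(object),
              nFaces(object)))
  if (length(object@faceLabels)) {
    tb <- table(object@faceLabels)
    cat("\n  face labels:",
        paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "))
  }
  bl <- tryCatch(length(boundaryLoops(object)), error = function(e) NA)
  cat(sprintf("\n  boundary loops: %s\n", bl))
  invisible(object)
})

setMethod("show", "Plane", function(object) {
  cat(sprintf("Plane: point (%.3f, %.3f, %.3f), normal (%.4f, %.4f, %.4f)\n",
              object@point[1], object@point[2], object@point[3],
              object@normal[1], object@normal[2], object@normal[3]))
  invisible(object)
})

setMethod("show", "SutureGeometry", function(object) {
  cat(sprintf(
    "SutureGeometry: alpha %.1f deg, beta %.1f deg, AB/AP %.3f, LP/AP %.3f\n",
    object@alpha, object@beta, object@abFrac, object@lpFrac))
  invisible(object)
})

setMethod("show", "PopulationParams", function(object) {
  cat(sprintf("PopulationParams: skin %.2f mm, skull %.2f mm, suture width %.1f mm\n",
              object@skinThickness, object@skullThickness, object@sutureWidth))
  show(object@suture)
  invisible(object)
})

setMethod("show", "ThicknessMap", function(object) {
  cat(sprintf("ThicknessMap: %d vertices, mean %.3f mm, sd %.3f mm\n",
              length(object@distances), object@mean, object@sd))
  invisible(object)
})

setMethod("show", "ShapeMetrics", function(object) {
  cat(sprintf("ShapeMetrics: BPD %.1f mm, OFD %.1f mm, CI %.3f\n",
              object@bpd, object@ofd, object@ci))
  invisible(object)
})

setMethod("show", "SkullModel", function(object) {
  cat(sprintf("SkullModel (%s): thickness %.2f mm, %d faces\n",
              object@provenance, object@thickness, nFaces(object@shell)))
  tb <- table(object@shell@faceLabels)
  cat("  regions:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "),
      "\n")
  if (length(object@springs))
    cat("  springs:", paste(vapply(object@springs, function(s) s@modelId, ""),
                            collapse = " + "), "\n")
  invisible(object)
})

setMethod("show", "FESystem", function(object) {
  cat(sprintf(
    "FESystem: %d vertices (%d ghost), %d faces, %d hinges, %d clamped\n",
    nrow(object@X0), nrow(object@X0) - object@nReal, nrow(object@faces),
    nrow(object@hinges), sum(object@fixed[seq_len(object@nReal)])))
  invisible(object)
})

setMethod("show", "ExpansionSolution", function(object) {
  tp <- object@timePoints
  op <- object@openings
  cat(sprintf("ExpansionSolution: %d time points, %d springs\n",
              length(tp), ncol(op)))
  for (nm in c("POSTOP", "FU")) {
    tt <- if (nm == "POSTOP") 1 else 432000
    i <- which.min(abs(tp - tt))
    cat(sprintf("  %s (t = %g s): openings %s mm\n", nm, tp[i],
                paste(sprintf("%.2f", op[i, ]), collapse = ", ")))
  }
  invisible(object)
})

#' Extract ShapeMetrics fields
#' @param x a [ShapeMetrics-class].
#' @return numeric(1).
#' @export
setGeneric("cephalicIndex", function(x) standardGeneric("cephalicIndex"))
#' @rdname cephalicIndex
#' @export
setMethod("cephalicIndex", "ShapeMetrics", function(x) x@ci)
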