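# Mesh, landmark and configuration I/O. Formats: STL (ASCII and binary),
# PLY (ASCII), OBJ for meshes; JSON for landmarks and labels; YAML/JSON for
# run configuration.

# merge exactly-duplicated vertices (STL stores each facet independently)
.weldVertices <- function(V, F) {
  key <- paste(V[, 1], V[, 2], V[, 3])
  first <- !duplicated(key)
  map <- match(key, key[first]) # welded (deduplicated) vertex index
  triSurface(V[first, , drop = FALSE], matrix(map[F], ncol = 3))
}

.readSTLBinary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!length(nf) || nf <= 0) stop(sprintf("I/O error: empty STL: %s", path))
  rec <- readBin(con, "raw", nf * 50)
  if (length(rec) < nf * 50) stop(sprintf("I/O error: truncated STL: %s", path))
  m <- matrix(rec, nrow = 50)
  tri <- vapply(seq_len(nf), function(i)
    readBin(m[13:48, i], "numeric", 9, size = 4, endian = "little"),
    numeric(9))
  V <- matrix(as.vector(tri), ncol = 3, byrow = TRUE)
  F <- matrix(seq_len(3 * nf), ncol = 3, byrow = TRUE)
  .weldVertices(V, F)
}

.readSTLAscii <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", ln, value = TRUE)
  if (!length(vl)) stop(sprintf("I/O error: no vertices in STL: %s", path))
  V <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  if (nrow(V) %% 3 != 0) stop(sprintf("I/O error: malformed STL: %s", path))
  F <- matrix(seq_len(nrow(V)), ncol = 3, byrow = TRUE)
  .weldVertices(V, F)
}

.readOBJ <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vt <- strsplit(trimws(grep("^v\\s", ln, value = TRUE)), "\\s+")
  ft <- strsplit(trimws(grep("^f\\s", ln, value = TRUE)), "\\s+")
  if (!length(vt) || !length(ft))
    stop(sprintf("I/O error: empty or faceless OBJ: %s", path))
  V <- do.call(rbind, lapply(vt, function(p) as.numeric(p[2:4])))
  F <- do.call(rbind, lapply(ft, function(p)
    as.integer(sub("/.*", "", p[2:4]))))
  triSurface(V, F)
}

.readPLY <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (!length(ln) || ln[1] != "ply")
    stop(sprintf("I/O error: not a PLY file: %s", path))
  endH <- match("end_header", ln)
  nv <- as.integer(sub(".*vertex\\s+", "",
                       grep("element vertex", ln[1:endH], value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "",
                       grep("element face", ln[1:endH], value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop(sprintf("I/O error: bad PLY header: %s", path))
  vRows <- ln[(endH + 1):(endH + nv)]
  fRows <- ln[(endH + nv + 1):(endH + nv + nf)]
  V <- do.call(rbind, lapply(strsplit(trimws(vRows), "\\s+"), function(p)
    as.numeric(p[1:3])))
  F <- do.call(rbind, lapply(strsplit(trimws(fRows), "\\s+"), function(p)
    as.integer(p[2:4]) + 1L))
  triSurface(V, F)
}

#' Read a triangle mesh (STL, PLY or OBJ)
#'
#' Format is chosen by extension; both binary and ASCII STL dialects are
#' detected. A sidecar label file `<path>.labels.json` written by
#' [writeMesh()] is picked up automatically.
#'
#' @param path file path.
#' @return a [TriSurface-class].
#' @export
readMesh <- function(path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop(sprintf("I/O error: unreadable or empty file: %s", path))
  ext <- tolower(tools::file_ext(path))
  mesh <- switch(ext,
    stl = {
      head <- readBin(path, "raw", 5)
      if (identical(rawToChar(head), "solid") &&
          length(grep("facet", readLines(path, n = 20, warn = FALSE))) > 0)
        .readSTLAscii(path)
      else .readSTLBinary(path)
    },
    obj = .readOBJ(path),
    ply = .readPLY(path),
    stop(sprintf("I/O error: unsupported mesh format '%s'", ext)))
  side <- paste0(path, ".labels.json")
  if (file.exists(side)) {
    lb <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(lb$faceLabels) && length(lb$faceLabels) == nFaces(mesh))
      mesh@faceLabels <- as.character(lb$faceLabels)
    if (!is.null(lb$vertexLabels) && length(lb$vertexLabels) == nVertices(mesh))
      mesh@vertexLabels <- as.character(lb$vertexLabels)
  }
  mesh
}

#' Write a triangle mesh (STL, PLY or OBJ)
#'
#' ASCII formats store coordinates with 9 significant digits, so a
#' write/read round trip preserves them to well below 1e-6 mm. Binary STL
#' stores IEEE float32 per the format definition (about 1e-5 mm at head
#' scale). Labels, if present, go to a `<path>.labels.json` sidecar.
#'
#' @param mesh a [TriSurface-class].
#' @param path output path, extension selects the format (`.stl`, `.ply`,
#'   `.obj`).
#' @param binary logical; write binary STL (ignored for other formats).
#' @return `path`, invisibly.
#' @export
writeMesh <- function(mesh, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  V <- mesh@vertices; F <- mesh@faces
  fmt <- function(x) sprintf("%.9g", x)
  if (ext == "stl" && binary) {
    con <- file(path, "wb")
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    fn <- faceNormals(mesh)
    for (i in seq_len(nrow(F))) {
      writeBin(as.numeric(c(fn[i, ], t(V[F[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
    close(con)
  } else if (ext == "stl") {
    fn <- faceNormals(mesh)
    out <- c("solid mesh",
             unlist(lapply(seq_len(nrow(F)), function(i) c(
               sprintf("  facet normal %s %s %s", fmt(fn[i, 1]), fmt(fn[i, 2]),
                       fmt(fn[i, 3])),
               "    outer loop",
               sprintf("      vertex %s %s %s", fmt(V[F[i, ], 1]),
                       fmt(V[F[i, ], 2]), fmt(V[F[i, ], 3])),
               "    endloop", "  endfacet"))),
             "endsolid mesh")
    writeLines(out, path)
  } else if (ext == "obj") {
    writeLines(c(sprintf("v %s %s %s", fmt(V[, 1]), fmt(V[, 2]), fmt(V[, 3])),
                 sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3])), path)
  } else if (ext == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(V)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(F)),
                 "property list uchar int vertex_indices", "end_header",
                 sprintf("%s %s %s", fmt(V[, 1]), fmt(V[, 2]), fmt(V[, 3])),
                 sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L)),
               path)
  } else stop(sprintf("I/O error: unsupported mesh format '%s'", ext))
  if (length(mesh@faceLabels) || length(mesh@vertexLabels))
    jsonlite::write_json(
      list(faceLabels = mesh@faceLabels, vertexLabels = mesh@vertexLabels),
      paste0(path, ".labels.json"))
  invisible(path)
}

#' Read anatomical landmarks from JSON
#'
#' The landmark file is the single coordinate-frame authority: keys
#' `nasion`, `tragion_left`, `tragion_right` (required), `bregma`, `lambda`
#' (optional), each an `[x, y, z]` triplet in mm in model coordinates, plus
#' an optional free-text `coordinate_frame` note.
#'
#' @param path JSON file path.
#' @return named list of numeric(3) (and the `coordinate_frame` note).
#' @export
readLandmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("I/O error: missing file: %s", path))
  lm <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("nasion", "tragion_left", "tragion_right")
  for (nm in need) {
    if (is.null(lm[[nm]]) || length(lm[[nm]]) != 3)
      stop(sprintf("I/O error: landmark '%s' missing or not length-3", nm))
    lm[[nm]] <- as.numeric(lm[[nm]])
  }
  for (nm in c("bregma", "lambda"))
    if (!is.null(lm[[nm]])) lm[[nm]] <- as.numeric(lm[[nm]])
  lm
}

#' Write anatomical landmarks to JSON
#' @param landmarks named list of numeric(3).
#' @param path output path.
#' @param note coordinate-frame note.
#' @return `path`, invisibly.
#' @export
writeLandmarks <- function(landmarks, path,
                           note = "model coordinates, mm, right-handed") {
  landmarks$coordinate_frame <- note
  jsonlite::write_json(landmarks, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
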