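# Mesh interchange: OFF, ASCII PLY, legacy ASCII VTK polydata (triangles
# only), plus a single-file JSON checkpoint container. All readers rebuild
# topology, refuse open or non-manifold surfaces, and flip globally to
# outward orientation (with a warning) when the file is wound inward.

.formatFromPath <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext, off = "off", ply = "ply", vtk = "vtk",
         stop("cannot infer mesh format from extension '", ext,
              "'; pass format = \"off\", \"ply\" or \"vtk\""))
}

#' Read a triangle mesh
#'
#' Reads a closed pure-triangle surface from OFF, ASCII PLY or legacy ASCII
#' VTK polydata. Faces with more than three vertices raise an error; open or
#' non-manifold surfaces are refused. If the file is wound inward (negative
#' signed volume) all faces are flipped to outward with a warning, so that
#' morphometry conventions hold.
#'
#' @param path file path.
#' @param format "off", "ply" or "vtk"; inferred from the extension by
#'   default.
#' @return a [TriangulatedMembrane-class].
#' @export
readMesh <- function(path, format = NULL) {
  if (is.null(format)) format <- .formatFromPath(path)
  format <- match.arg(tolower(format), c("off", "ply", "vtk"))
  parsed <- switch(format,
    off = .readOFF(path),
    ply = .readPLY(path),
    vtk = .readVTK(path))
  buildMembrane(parsed$vertices, parsed$triangles,
                metadata = list(source = path), orientation = "warn")
}

#' Write a triangle mesh
#'
#' Writes OFF, ASCII PLY or legacy ASCII VTK polydata. Vertex coordinates are
#' written with 9 significant digits so that write-then-read round-trips
#' coordinates to that precision and connectivity exactly. For VTK, named
#' per-vertex scalar fields (e.g. the vertex curvature) can be attached as
#' POINT_DATA for visualisation.
#'
#' @param mesh a [TriangulatedMembrane-class].
#' @param path output path.
#' @param format "off", "ply" or "vtk"; inferred from the extension by
#'   default.
#' @param pointData optional named list of per-vertex numeric vectors
#'   (VTK only).
#' @return the path, invisibly.
#' @export
writeMesh <- function(mesh, path, format = NULL, pointData = NULL) {
  stopifnot(is(mesh, "TriangulatedMembrane"))
  if (is.null(format)) format <- .formatFromPath(path)
  format <- match.arg(tolower(format), c("off", "ply", "vtk"))
  if (!is.null(pointData) && format != "vtk")
    stop("pointData fields are supported for VTK output only")
  switch(format,
    off = .writeOFF(mesh, path),
    ply = .writePLY(mesh, path),
    vtk = .writeVTK(mesh, path, pointData))
  invisible(path)
}

.fmtCoords <- function(v) {
  apply(v, 1L, function(r) paste(formatC(r, digits = 9, format = "g"), collapse = " "))
}

.readTokens <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  lines
}

.writeOFF <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d %d", nVertices(mesh), nTriangles(mesh), nEdges(mesh)), con)
  writeLines(.fmtCoords(mesh@vertices), con)
  writeLines(paste("3", mesh@triangles[, 1L] - 1L, mesh@triangles[, 2L] - 1L,
                   mesh@triangles[, 3L] - 1L), con)
}

.readOFF <- function(path) {
  lines <- .readTokens(path)
  if (!grepl("^OFF", lines[1L])) stop("not an OFF file: missing OFF header")
  counts <- scan(text = lines[2L], quiet = TRUE)
  nV <- counts[1L]; nF <- counts[2L]
  vtx <- matrix(scan(text = lines[3:(2 + nV)], quiet = TRUE), ncol = 3L, byrow = TRUE)
  facelines <- lines[(3 + nV):(2 + nV + nF)]
  .parseCountedFaces(facelines, "OFF")
  faces <- matrix(scan(text = facelines, quiet = TRUE), ncol = 4L, byrow = TRUE)
  list(vertices = vtx, triangles = faces[, 2:4, drop = FALSE] + 1L)
}

# shared guard: every face line must start with vertex count 3
.parseCountedFaces <- function(facelines, what) {
  counts <- as.integer(sub("^\\s*(\\d+).*", "\\1", facelines))
  if (any(counts != 3L))
    stop(sprintf("%s file contains non-triangular faces (%d vertices); only triangle surfaces are supported",
                 what, counts[which(counts != 3L)[1L]]))
  invisible(TRUE)
}

.writePLY <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0", "comment rbcshape membrane mesh",
               sprintf("element vertex %d", nVertices(mesh)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nTriangles(mesh)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(.fmtCoords(mesh@vertices), con)
  writeLines(paste("3", mesh@triangles[, 1L] - 1L, mesh@triangles[, 2L] - 1L,
                   mesh@triangles[, 3L] - 1L), con)
}

.readPLY <- function(path) {
  lines <- readLines(path, warn = FALSE)
  endh <- match("end_header", trimws(lines))
  if (is.na(endh) || tolower(trimws(lines[1L])) != "ply")
    stop("not an ASCII PLY file")
  header <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format\\s+ascii", header)))
    stop("only ASCII PLY is supported")
  nV <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", header, value = TRUE)))
  nF <- as.integer(sub("^element face\\s+", "", grep("^element face", header, value = TRUE)))
  body <- lines[-seq_len(endh)]
  body <- body[nzchar(trimws(body))]
  vtx <- matrix(scan(text = body[seq_len(nV)], quiet = TRUE), ncol = 3L, byrow = TRUE)[, 1:3, drop = FALSE]
  facelines <- body[nV + seq_len(nF)]
  .parseCountedFaces(facelines, "PLY")
  faces <- matrix(scan(text = facelines, quiet = TRUE), ncol = 4L, byrow = TRUE)
  list(vertices = vtx, triangles = faces[, 2:4, drop = FALSE] + 1L)
}

.writeVTK <- function(mesh, path, pointData = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "rbcshape membrane mesh",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d double", nVertices(mesh))), con)
  writeLines(.fmtCoords(mesh@vertices), con)
  nT <- nTriangles(mesh)
  writeLines(sprintf("POLYGONS %d %d", nT, 4L * nT), con)
  writeLines(paste("3", mesh@triangles[, 1L] - 1L, mesh@triangles[, 2L] - 1L,
                   mesh@triangles[, 3L] - 1L), con)
  if (!is.null(pointData)) {
    writeLines(sprintf("POINT_DATA %d", nVertices(mesh)), con)
    for (nm in names(pointData)) {
      vals <- pointData[[nm]]
      stopifnot(length(vals) == nVertices(mesh))
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(formatC(vals, digits = 9, format = "g"), con)
    }
  }
}

.readVTK <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!grepl("^# vtk DataFile", lines[1L])) stop("not a legacy VTK file")
  if (!any(toupper(trimws(lines)) == "ASCII")) stop("only ASCII VTK is supported")
  ds <- grep("^DATASET", toupper(lines))
  if (!length(ds) || !grepl("POLYDATA", toupper(lines[ds[1L]])))
    stop("only VTK POLYDATA is supported")
  ip <- grep("^POINTS", lines)
  nV <- as.integer(strsplit(trimws(lines[ip[1L]]), "\\s+")[[1L]][2L])
  # points may wrap across lines: scan tokens until 3 nV numbers are read
  coords <- numeric(0); i <- ip[1L] + 1L
  while (length(coords) < 3L * nV) {
    coords <- c(coords, scan(text = lines[i], quiet = TRUE))
    i <- i + 1L
  }
  vtx <- matrix(coords, ncol = 3L, byrow = TRUE)
  ipoly <- grep("^POLYGONS", lines)
  if (!length(ipoly)) stop("VTK file has no POLYGONS block")
  hdr <- strsplit(trimws(lines[ipoly[1L]]), "\\s+")[[1L]]
  nF <- as.integer(hdr[2L]); total <- as.integer(hdr[3L])
  ints <- integer(0); i <- ipoly[1L] + 1L
  while (length(ints) < total) {
    ints <- c(ints, as.integer(scan(text = lines[i], quiet = TRUE)))
    i <- i + 1L
  }
  faces <- matrix(NA_integer_, nF, 3L)
  pos <- 1L
  for (f in seq_len(nF)) {
    cnt <- ints[pos]
    if (cnt != 3L)
      stop(sprintf("VTK file contains non-triangular faces (%d vertices); only triangle surfaces are supported", cnt))
    faces[f, ] <- ints[(pos + 1L):(pos + 3L)]
    pos <- pos + cnt + 1L
  }
  list(vertices = vtx, triangles = faces + 1L)
}

#' Save or load a mesh checkpoint
#'
#' A single-file hierarchical container (JSON) with named arrays
#' (\code{positions}, \code{triangles}), optional per-vertex velocities, and
#' a metadata block (units, construction parameters). Round-trips topology
#' exactly and coordinates at full double precision.
#'
#' @param mesh a [TriangulatedMembrane-class].
#' @param path checkpoint path (.json).
#' @param velocities optional nV x 3 matrix stored alongside.
#' @return \code{writeCheckpoint} the path invisibly; \code{readCheckpoint} a
#'   list with elements \code{mesh} and (possibly NULL) \code{velocities}.
#' @export
writeCheckpoint <- function(mesh, path, velocities = NULL) {
  stopifnot(is(mesh, "TriangulatedMembrane"))
  payload <- list(
    format = "rbcshape-checkpoint-1",
    units = list(coordinates = "micrometre"),
    positions = mesh@vertices,
    triangles = mesh@triangles,
    metadata = mesh@metadata
  )
  if (!is.null(velocities)) payload$velocities <- velocities
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "rbcshape-checkpoint-1"))
    stop("not an rbcshape checkpoint file")
  md <- payload$metadata
  if (is.null(md)) md <- list()
  mesh <- buildMembrane(payload$positions, payload$triangles, metadata = as.list(md))
  vel <- payload$velocities
  if (!is.null(vel)) vel <- as.matrix(vel)
  list(mesh = mesh, velocities = vel)
}
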