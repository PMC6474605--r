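# Discrete geometry on the triangulated membrane: areas, volume, dihedral
# edge curvature, leaflet area difference, total curvature, vertex curvature,
# principal extents and assembled shape metrics.

# row-wise cross product of n x 3 matrices
.rowCross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Sign convention for the dihedral angle: theta > 0 where the triangle pair
# is convex as seen from outside (a sphere is positive everywhere), theta < 0
# in concave invaginations. With T1 holding the directed edge a->b and
# outward normals n1, n2, this is theta = atan2((n1 x n2) . e_hat, n1 . n2).
.triangleGeometry <- function(v, tri) {
  p1 <- v[tri[, 1L], , drop = FALSE]
  p2 <- v[tri[, 2L], , drop = FALSE]
  p3 <- v[tri[, 3L], , drop = FALSE]
  n <- .rowCross(p2 - p1, p3 - p1)
  nn <- sqrt(rowSums(n^2))
  areas <- nn / 2
  bad <- which(areas < 1e-12)
  if (length(bad))
    stop(sprintf("degenerate (zero-area) triangle: index %d", bad[1L]))
  list(areas = areas, normals = n / nn)
}

#' Per-edge discrete geometry
#'
#' Computes, for every unique edge of a closed outward-oriented mesh, the
#' length l_j, the signed dihedral angle theta_j between the outward unit
#' normals of the two incident triangles, the edge curvature
#' M_j = l_j theta_j / 2 and the edge-associated area
#' dA_j = (A_T1 + A_T2)/3. Positive theta_j (hence M_j) marks locally convex
#' surface (sphere, spicule tips), negative marks concave invaginations;
#' the sum of M_j approximates the integrated mean curvature, and the sum of
#' dA_j equals the surface area exactly.
#'
#' @param mesh a [TriangulatedMembrane-class].
#' @return an [EdgeGeometry-class].
#' @export
edgeGeometry <- function(mesh) {
  stopifnot(is(mesh, "TriangulatedMembrane"))
  v <- mesh@vertices
  tg <- .triangleGeometry(v, mesh@triangles)
  ed <- mesh@edges; et <- mesh@edgeTriangles
  evec <- v[ed[, 2L], , drop = FALSE] - v[ed[, 1L], , drop = FALSE]
  len <- sqrt(rowSums(evec^2))
  n1 <- tg$normals[et[, 1L], , drop = FALSE]
  n2 <- tg$normals[et[, 2L], , drop = FALSE]
  s <- rowSums(.rowCross(n1, n2) * evec) / len
  cth <- rowSums(n1 * n2)
  theta <- atan2(s, cth)
  dAj <- (tg$areas[et[, 1L]] + tg$areas[et[, 2L]]) / 3
  new("EdgeGeometry",
      lengths = len, dihedrals = theta, edgeCurvature = len * theta / 2,
      edgeArea = dAj, triangleAreas = tg$areas, triangleNormals = tg$normals)
}

#' @rdname surfaceArea
#' @export
setMethod("surfaceArea", "TriangulatedMembrane", function(x) {
  sum(.triangleGeometry(x@vertices, x@triangles)$areas)
})

#' @rdname enclosedVolume
#' @export
setMethod("enclosedVolume", "TriangulatedMembrane", function(x) {
  .signedVolume(x@vertices, x@triangles)
})

#' Bilayer-leaflet area difference
#'
#' dA = 2 D0 sum_j M_j: the (signed) area by which the outer leaflet exceeds
#' the inner one, from the discrete integrated mean curvature and the
#' monolayer thickness D0. A sphere of radius R gives 8 pi R D0.
#'
#' @param geom an [EdgeGeometry-class] (or a mesh, which is measured first).
#' @param D0 monolayer thickness, micrometres (physiological 2 nm = 0.002).
#' @return numeric scalar, square micrometres, signed.
#' @export
bilayerAreaDifference <- function(geom, D0) {
  if (is(geom, "TriangulatedMembrane")) geom <- edgeGeometry(geom)
  stopifnot(is(geom, "EdgeGeometry"), D0 > 0)
  2 * D0 * sum(geom@edgeCurvature)
}

#' Total membrane curvature
#'
#' C = 2 D0 sum_j |M_j|: the direction-independent analogue of the leaflet
#' area difference. C >= |dA| always, with equality exactly when every
#' triangle pair bends the same way (e.g. a convex body).
#'
#' @inheritParams bilayerAreaDifference
#' @return numeric scalar, square micrometres, non-negative.
#' @export
totalMembraneCurvature <- function(geom, D0) {
  if (is(geom, "TriangulatedMembrane")) geom <- edgeGeometry(geom)
  stopifnot(is(geom, "EdgeGeometry"), D0 > 0)
  2 * D0 * sum(abs(geom@edgeCurvature))
}

#' Per-vertex membrane curvature
#'
#' The curvature field CV_i on membrane vertices, from the edge curvatures of
#' the links meeting at each vertex. The default (area-normalised) form
#' CV_i = sum(M_j) / sum(dA_j) over incident edges converges to the mean
#' curvature on smooth surfaces (1/R on a sphere, in 1/micrometre);
#' \code{normalized = FALSE} gives the per-link sum of M_j/dA_j instead,
#' which scales with vertex valence and is kept only for sensitivity checks.
#' Positive values mark convex regions (spicule tips), negative values
#' concave ones (dimples, invaginations).
#'
#' @param mesh a [TriangulatedMembrane-class].
#' @param geom optional precomputed [EdgeGeometry-class] for the same mesh.
#' @param normalized logical; see above.
#' @return numeric vector, one value per vertex, 1/micrometre.
#' @export
vertexCurvature <- function(mesh, geom = NULL, normalized = TRUE) {
  stopifnot(is(mesh, "TriangulatedMembrane"))
  if (is.null(geom)) geom <- edgeGeometry(mesh)
  nV <- nVertices(mesh)
  idx <- c(mesh@edges[, 1L], mesh@edges[, 2L])
  M <- rep(geom@edgeCurvature, 2L)
  dA <- rep(geom@edgeArea, 2L)
  if (normalized) {
    num <- vapply(split(M, idx), sum, 0)
    den <- vapply(split(dA, idx), sum, 0)
    cv <- rep(NA_real_, nV)
    cv[as.integer(names(num))] <- num / den
  } else {
    r <- vapply(split(M / dA, idx), sum, 0)
    cv <- rep(NA_real_, nV)
    cv[as.integer(names(r))] <- r
  }
  if (anyNA(cv)) stop("mesh has isolated vertices")
  cv
}

#' Principal-axis extents
#'
#' Treats the surface as a rigid thin shell of uniform density: the
#' area-weighted centre of mass and second-moment tensor are integrated
#' exactly over every triangle (midpoint quadrature, exact for quadratics),
#' and the extents H1 <= H2 <= H3 are the peak-to-peak spans of the vertices
#' projected on the three principal axes.
#'
#' @param mesh a [TriangulatedMembrane-class].
#' @return numeric length 3: sorted extents, micrometres.
#' @export
principalExtents <- function(mesh) {
  stopifnot(is(mesh, "TriangulatedMembrane"))
  v <- mesh@vertices; tri <- mesh@triangles
  tg <- .triangleGeometry(v, tri)
  A <- tg$areas
  p1 <- v[tri[, 1L], , drop = FALSE]
  p2 <- v[tri[, 2L], , drop = FALSE]
  p3 <- v[tri[, 3L], , drop = FALSE]
  ctr <- colSums(A * (p1 + p2 + p3) / 3) / sum(A)
  m12 <- sweep((p1 + p2) / 2, 2L, ctr)
  m23 <- sweep((p2 + p3) / 2, 2L, ctr)
  m31 <- sweep((p3 + p1) / 2, 2L, ctr)
  S <- (crossprod(m12 * A, m12) + crossprod(m23 * A, m23) +
        crossprod(m31 * A, m31)) / 3
  ax <- eigen(S, symmetric = TRUE)$vectors
  proj <- sweep(v, 2L, ctr) %*% ax
  sort(apply(proj, 2L, function(x) diff(range(x))))
}

#' Full shape morphometry
#'
#' Assembles every scalar descriptor of a closed membrane mesh: area A,
#' volume V, reduced volume nu = V / ((4/3) pi R*^3) relative to the sphere
#' of equal area (R* = sqrt(A/4 pi)), leaflet area difference dA, total
#' curvature C, principal extents H1 <= H2 <= H3, normalised length
#' Hx = H3/R*, normalised thickness Hz = H1/R*, shape factor
#' SF = H1/sqrt(H2 H3) (1 for a sphere, toward 0 for a flat disc) and the
#' per-vertex curvature field.
#'
#' @param mesh a [TriangulatedMembrane-class].
#' @param D0 monolayer thickness, micrometres (default 0.002).
#' @return a [ShapeMetrics-class].
#' @examples
#' sm <- shapeMetrics(buildIcosphere(140, 2))
#' sm@reducedVolume  # ~1 for a sphere
#' @export
shapeMetrics <- function(mesh, D0 = 0.002) {
  stopifnot(is(mesh, "TriangulatedMembrane"))
  geom <- edgeGeometry(mesh)
  A <- sum(geom@triangleAreas)
  V <- enclosedVolume(mesh)
  Rstar <- sqrt(A / (4 * pi))
  H <- principalExtents(mesh)
  new("ShapeMetrics",
      area = A, volume = V,
      reducedVolume = V / ((4 / 3) * pi * Rstar^3),
      areaDifference = bilayerAreaDifference(geom, D0),
      totalCurvature = totalMembraneCurvature(geom, D0),
      extents = H, Hx = H[3L] / Rstar, Hz = H[1L] / Rstar,
      SF = H[1L] / sqrt(H[2L] * H[3L]),
      Rstar = Rstar, D0 = D0,
      vertexCurvature = vertexCurvature(mesh, geom))
}

#' Percentage-error comparison of two shapes
#'
#' epsilon = 100 |predicted - reference| / |reference| for the cellular
#' measurements Hx, Hz and SF (and, when \code{extended}, also the reduced
#' volume and the area-normalised dA and C).
#'
#' @param reference,predicted [ShapeMetrics-class] objects measured with the
#'   same conventions.
#' @param extended include nu, dA/A and C/A (default FALSE).
#' @return named numeric vector of percentage errors.
#' @export
compareShapes <- function(reference, predicted, extended = FALSE) {
  stopifnot(is(reference, "ShapeMetrics"), is(predicted, "ShapeMetrics"))
  pick <- function(ref, prd) {
    if (abs(ref) < .Machine$double.xmin)
      stop("reference value is zero; percentage error undefined")
    100 * abs(prd - ref) / abs(ref)
  }
  out <- c(Hx = pick(reference@Hx, predicted@Hx),
           Hz = pick(reference@Hz, predicted@Hz),
           SF = pick(reference@SF, predicted@SF))
  if (extended) {
    out <- c(out,
      nu = pick(reference@reducedVolume, predicted@reducedVolume),
      dA_over_A = pick(reference@areaDifference / reference@area,
                       predicted@areaDifference / predicted@area),
      C_over_A = pick(reference@totalCurvature / reference@area,
                      predicted@totalCurvature / predicted@area))
  }
  out
}

#' Export shape metrics as a flat table
#'
#' One row per scalar descriptor with value and unit; written as CSV when
#' \code{path} is given, and convertible to JSON downstream.
#'
#' @param metrics a [ShapeMetrics-class].
#' @param path optional CSV path.
#' @return data.frame (invisibly when written).
#' @export
metricsTable <- function(metrics, path = NULL) {
  stopifnot(is(metrics, "ShapeMetrics"))
  df <- data.frame(
    quantity = c("area", "volume", "reduced_volume", "area_difference",
                 "total_curvature", "H1", "H2", "H3", "Hx", "Hz", "SF",
                 "Rstar", "D0", "CV_min", "CV_max"),
    value = c(metrics@area, metrics@volume, metrics@reducedVolume,
              metrics@areaDifference, metrics@totalCurvature,
              metrics@extents, metrics@Hx, metrics@Hz, metrics@SF,
              metrics@Rstar, metrics@D0,
              min(metrics@vertexCurvature), max(metrics@vertexCurvature)),
    unit = c("um^2", "um^3", "1", "um^2", "um^2", "um", "um", "um",
             "1", "1", "1", "um", "um", "1/um", "1/um"),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}

setMethod("show", "ShapeMetrics", function(object) {
  cat("ShapeMetrics\n")
  cat(sprintf("  A = %.4g um^2, V = %.4g um^3, nu = %.4f\n",
              object@area, object@volume, object@reducedVolume))
  cat(sprintf("  dA = %.4g um^2, C = %.4g um^2 (D0 = %g um)\n",
              object@areaDifference, object@totalCurvature, object@D0))
  cat(sprintf("  extents H1..H3 = %.3f, %.3f, %.3f um\n",
              object@extents[1], object@extents[2], object@extents[3]))
  cat(sprintf("  Hx = %.4f, Hz = %.4f, SF = %.4f\n",
              object@Hx, object@Hz, object@SF))
  cat(sprintf("  vertex curvature range: [%.3f, %.3f] 1/um\n",
              min(object@vertexCurvature), max(object@vertexCurvature)))
})
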