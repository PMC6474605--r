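# Shape-prediction experiments: single relaxation points, sweeps over the
# (dA0/A0, C0/A0) plane, reduced-volume and elastic-length-scale studies,
# measurement of external meshes, and a heuristic shape classifier for
# sweep summaries.

#' Elastic length scale
#'
#' Lambda_el = sqrt(kappa / mu0): the length below which bending resistance
#' dominates cytoskeletal shear, governing spicule sharpness. The
#' physiological pair kappa = 2.5e-19 N m, mu0 = 4.0e-6 N/m gives 0.25
#' micrometres.
#'
#' @param kappa bending modulus, N m.
#' @param mu0 shear modulus, N/m.
#' @return length in micrometres.
#' @examples
#' elasticLengthScale(2.5e-19, 4.0e-6)  # 0.25
#' @export
elasticLengthScale <- function(kappa, mu0) {
  if (any(kappa <= 0) || any(mu0 <= 0)) stop("kappa and mu0 must be positive")
  sqrt(kappa / mu0) * 1e6
}

#' Relax one experiment point
#'
#' Builds the constraint set from a reduced volume and the leaflet
#' area-difference and total-curvature targets quoted as percentages of the
#' reference area, calibrates the spectrin network on the cytoskeletal
#' reference state, relaxes a (perturbed) icosphere of the reference area,
#' and measures the relaxed shape.
#'
#' @param reference a [CytoskeletonReference-class]; supplies A0, the
#'   per-link rest lengths and per-triangle reference areas (and the mesh
#'   resolution).
#' @param nu target reduced cell volume (0.6 physiological).
#' @param dA0Percent leaflet area-difference target, percent of A0
#'   (sweep range 0.05-0.30).
#' @param C0Percent total-curvature target, percent of A0 (sweep range
#'   0.30-0.90).
#' @param mu0Multiplier scales the physiological shear modulus 4.0e-6 N/m;
#'   multipliers 5, 2, 1, 0.5, 0.2 give elastic length scales 0.11, 0.18,
#'   0.25, 0.35, 0.56 micrometres at the default bending modulus.
#' @param model an [EnergyModel-class] (default [energyModel()]).
#' @param config a [DynamicsConfig-class].
#' @param D0Metrics monolayer thickness for morphometry, micrometres.
#' @return a list with elements \code{spec} (the resolved parameters),
#'   \code{state} (the [SimulationState-class]), \code{metrics}
#'   (the [ShapeMetrics-class] of the relaxed mesh) and \code{energy}
#'   (final [EnergyBreakdown-class]).
#' @export
runPoint <- function(reference, nu, dA0Percent, C0Percent,
                     mu0Multiplier = 1, model = energyModel(),
                     config = dynamicsConfig(), D0Metrics = model@D0 / 1e-6) {
  stopifnot(is(reference, "CytoskeletonReference"))
  if (C0Percent < dA0Percent)
    warning("C0/A0 below dA0/A0: total curvature can never be smaller than |dA|")
  A0 <- reference@A0
  Rrbc <- sqrt(A0 / (4 * pi))
  mu0 <- 4.0e-6 * mu0Multiplier
  spectrin <- calibrateSpectrin(mu0, l0 = reference@l0)
  constraints <- referenceConstraints(
    A0 = A0, V0 = nu * (4 / 3) * pi * Rrbc^3, Ak0 = reference@Ak0,
    dA0Percent = dA0Percent, C0Percent = C0Percent)
  level <- reference@membrane@metadata$level
  start <- buildIcosphere(A0, if (is.null(level)) 3L else level)
  state <- relaxMembrane(start, spectrin, model, constraints, config)
  metrics <- shapeMetrics(state@membrane, D0 = D0Metrics)
  e <- state@energyHistory
  spec <- list(nu = nu, dA0Percent = dA0Percent, C0Percent = C0Percent,
               mu0 = mu0, mu0Multiplier = mu0Multiplier,
               lambdaEl = elasticLengthScale(model@kappa, mu0),
               A0 = A0, seed = config@seed, mode = config@mode,
               level = level)
  list(spec = spec, state = state, metrics = metrics,
       energy = .breakdownFromVector(unlist(
         e[nrow(e), c("stretching", "bending", "surfaceArea", "volume",
                      "areaDifference", "totalCurvature")])))
}

#' Run a sweep of experiment points
#'
#' Executes [runPoint()] for every row of a grid; points are independent
#' (results do not depend on execution order) and failures are tolerated and
#' flagged per point.
#'
#' @param reference a [CytoskeletonReference-class].
#' @param grid data.frame with columns \code{nu}, \code{dA0Percent},
#'   \code{C0Percent} and optionally \code{mu0Multiplier}.
#' @param model,config,D0Metrics passed to [runPoint()].
#' @return data.frame: the grid plus convergence flag, the shape
#'   descriptors, curvature extrema, protrusion count and final energies;
#'   full point results in \code{attr(, "points")}.
#' @export
runSweep <- function(reference, grid, model = energyModel(),
                     config = dynamicsConfig(), D0Metrics = model@D0 / 1e-6) {
  stopifnot(all(c("nu", "dA0Percent", "C0Percent") %in% names(grid)))
  if (is.null(grid$mu0Multiplier)) grid$mu0Multiplier <- 1
  points <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch(
      runPoint(reference, grid$nu[i], grid$dA0Percent[i], grid$C0Percent[i],
               mu0Multiplier = grid$mu0Multiplier[i], model = model,
               config = config, D0Metrics = D0Metrics),
      error = function(e) e)
    points[[i]] <- res
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(grid[i, , drop = FALSE], converged = NA,
                              failed = TRUE, Hx = NA, Hz = NA, SF = NA,
                              nuAchieved = NA, dAPercent = NA, CPercent = NA,
                              cvMin = NA, cvMax = NA, protrusions = NA,
                              totalEnergy = NA)
    } else {
      m <- res$metrics
      rows[[i]] <- data.frame(
        grid[i, , drop = FALSE], converged = res$state@converged,
        failed = FALSE, Hx = m@Hx, Hz = m@Hz, SF = m@SF,
        nuAchieved = m@reducedVolume,
        dAPercent = 100 * m@areaDifference / m@area,
        CPercent = 100 * m@totalCurvature / m@area,
        cvMin = min(m@vertexCurvature), cvMax = max(m@vertexCurvature),
        protrusions = countProtrusions(res$state@membrane, m),
        totalEnergy = res$energy@total)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "points") <- points
  out
}

#' Default transect across the shape-transformation plane
#'
#' An n-point straight path across the sweep ranges dA0/A0 = 0.05-0.30
#' percent and C0/A0 = 0.30-0.90 percent at fixed reduced volume: the low
#' end relaxes to stomatocytes (inward curvature), the middle to the
#' biconcave discocyte, the high end to echinocytes (spicules). Endpoints
#' illustrative - the mapping of stages to exact pairs is not unique.
#'
#' @param n number of points (default 9).
#' @param nu reduced volume for every point (default 0.6).
#' @return data.frame usable with [runSweep()].
#' @export
sdeTransect <- function(n = 9L, nu = 0.6) {
  data.frame(nu = nu,
             dA0Percent = seq(0.05, 0.30, length.out = n),
             C0Percent = seq(0.30, 0.90, length.out = n))
}

#' Count convex protrusions (spicules)
#'
#' Heuristic spicule counter for sweep summaries: vertices whose curvature
#' exceeds \code{threshold} (default twice the equal-area sphere curvature
#' 1/R*) are clustered into connected components over the mesh edges; the
#' count of components is returned. Labelled heuristic: it ranks shapes
#' along the stomatocyte-discocyte-echinocyte ladder but is no substitute
#' for inspection.
#'
#' @param mesh a [TriangulatedMembrane-class].
#' @param metrics optional precomputed [ShapeMetrics-class].
#' @param threshold curvature threshold, 1/micrometre; default 2/R*.
#' @param sign "positive" counts convex protrusions (spicules),
#'   "negative" concave invaginations (stomatocyte mouths, dimples).
#' @return integer component count.
#' @export
countProtrusions <- function(mesh, metrics = NULL, threshold = NULL,
                             sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (is.null(metrics)) metrics <- shapeMetrics(mesh)
  cv <- metrics@vertexCurvature
  if (sign == "negative") cv <- -cv
  if (is.null(threshold)) threshold <- 2 / metrics@Rstar
  marked <- which(cv > threshold)
  if (!length(marked)) return(0L)
  inset <- logical(nVertices(mesh))
  inset[marked] <- TRUE
  # union-find over mesh edges restricted to marked vertices
  parent <- seq_len(nVertices(mesh))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ed <- mesh@edges
  keep <- inset[ed[, 1L]] & inset[ed[, 2L]]
  for (e in which(keep)) {
    ra <- find(ed[e, 1L]); rb <- find(ed[e, 2L])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(marked, find, 1L)))
}

#' Classify a relaxed shape along the SDE ladder
#'
#' Coarse heuristic classification from the vertex-curvature field:
#' dominant deep negative curvature marks stomatocytes, many distinct
#' convex protrusions mark echinocytes, and a biconcave signature (exactly
#' the two dimples of negative curvature on an otherwise smooth surface)
#' marks the discocyte.
#'
#' @param mesh a [TriangulatedMembrane-class].
#' @param metrics optional precomputed [ShapeMetrics-class].
#' @return one of "stomatocyte", "discocyte", "echinocyte", "sphere-like".
#' @export
classifyShape <- function(mesh, metrics = NULL) {
  if (is.null(metrics)) metrics <- shapeMetrics(mesh)
  cv <- metrics@vertexCurvature
  h0 <- 1 / metrics@Rstar
  nSpic <- countProtrusions(mesh, metrics, sign = "positive")
  nDimp <- countProtrusions(mesh, metrics, sign = "negative",
                            threshold = 0.5 / metrics@Rstar)
  if (nSpic >= 4L) return("echinocyte")
  if (min(cv) < -2 * h0 || (nDimp >= 1L && abs(min(cv)) > max(cv) - h0))
    return("stomatocyte")
  if (nDimp >= 1L && metrics@SF < 0.6) return("discocyte")
  if (metrics@reducedVolume > 0.95) return("sphere-like")
  if (metrics@SF < 0.6) return("discocyte")
  "sphere-like"
}

#' Measure an external cell surface
#'
#' The pathway for confocal-derived (or any external) triangulated cell
#' surfaces: read the mesh, refuse open or non-manifold surfaces, and return
#' the full morphometry - area, volume, reduced volume relative to the
#' equal-area sphere, leaflet area difference, total curvature, extents and
#' shape factor. The area-normalised dA/A and C/A and the reduced volume can
#' then be fed back to [runPoint()] to predict the matching model shape.
#'
#' @param path mesh file (OFF, PLY or VTK).
#' @param D0 monolayer thickness, micrometres (default 0.002).
#' @param format optional explicit format.
#' @return a [ShapeMetrics-class].
#' @export
measureExternal <- function(path, D0 = 0.002, format = NULL) {
  shapeMetrics(readMesh(path, format), D0 = D0)
}

#' Run manifest
#'
#' All resolved parameters of an experiment point plus seed, mode and
#' convergence outcome, serialised as JSON next to the run outputs.
#'
#' @param point result of [runPoint()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
runManifest <- function(point, path) {
  m <- point$metrics
  jsonlite::write_json(list(
    package = "rbcshape",
    version = as.character(utils::packageVersion("rbcshape")),
    spec = point$spec,
    converged = point$state@converged,
    iterations = point$state@iterations,
    metrics = list(Hx = m@Hx, Hz = m@Hz, SF = m@SF,
                   nu = m@reducedVolume, area = m@area, volume = m@volume,
                   dA = m@areaDifference, C = m@totalCurvature)
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
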