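# Relaxation toward the minimum free-energy shape: analytic forces by
# virtual work, damped time stepping with an adaptive displacement-capped
# step, per-component energy convergence.

.spectrinList <- function(params) {
  list(l0 = params@l0, lmax = params@lmax, kp = params@kp,
       p = params@p, kBT = params@kBT, m = params@m)
}

.modelList <- function(model) {
  list(kappa = model@kappa, kA = model@kA, ka = model@ka, kv = model@kv,
       kad = model@kad, kC = model@kC, D0 = model@D0)
}

.constraintListSI <- function(constraints) {
  list(A0 = constraints@A0 * .UM2, V0 = constraints@V0 * .UM3,
       Ak0 = constraints@Ak0 * .UM2, dA0 = constraints@dA0 * .UM2,
       C0 = constraints@C0 * .UM2)
}

.expandSpectrin <- function(params, nE) {
  params@l0 <- rep_len(params@l0, nE)
  params@lmax <- rep_len(params@lmax, nE)
  params@kp <- rep_len(params@kp, nE)
  params
}

.breakdownFromVector <- function(e) {
  new("EnergyBreakdown",
      stretching = e[["stretching"]], bending = e[["bending"]],
      surfaceArea = e[["surfaceArea"]], volume = e[["volume"]],
      areaDifference = e[["areaDifference"]],
      totalCurvature = e[["totalCurvature"]], total = sum(e))
}

#' Forces on membrane vertices
#'
#' Analytic gradient of the full free energy ([totalEnergy()]) with respect
#' to every vertex position, by the principle of virtual work
#' (F_i = -dE/dr_i). Translation and rotation invariance of the energy make
#' the net force and torque vanish.
#'
#' @param mesh a [TriangulatedMembrane-class].
#' @param spectrin a [SpectrinParams-class].
#' @param model an [EnergyModel-class].
#' @param constraints a [ReferenceConstraints-class].
#' @return numeric matrix (nV x 3) of forces in newtons, with attribute
#'   \code{"energy"} holding the [EnergyBreakdown-class] at this
#'   configuration.
#' @export
computeForces <- function(mesh, spectrin, model, constraints) {
  stopifnot(is(mesh, "TriangulatedMembrane"))
  spectrin <- .expandSpectrin(spectrin, nEdges(mesh))
  res <- .energyForcesCpp(mesh@vertices * .UM, mesh@triangles, mesh@edges,
                          mesh@edgeTriangles, mesh@edgeOpposite,
                          .spectrinList(spectrin), .modelList(model),
                          .constraintListSI(constraints), forces = TRUE)
  f <- res$forces
  attr(f, "energy") <- .breakdownFromVector(res$energy)
  f
}

#' Relaxation dynamics configuration
#'
#' See [DynamicsConfig-class] for the meaning of every field. Defaults give
#' the overdamped first-order descent whose equilibrium is independent of
#' the damping constant and particle mass.
#'
#' @param mass particle mass, kg (default 1e-9; as-printed mode only).
#' @param damping viscosity c (default 1e-7: N s/m in overdamped mode, the
#'   dimensionless velocity-damping factor in as-printed mode).
#' @param dt fixed time step in seconds, or NA (default) for adaptive.
#' @param dtSafety per-step displacement cap as a fraction of the minimum
#'   edge length (default 0.05).
#' @param maxIterations iteration budget (default 200000).
#' @param convergenceTol per-component relative energy tolerance
#'   (default 1e-7).
#' @param checkInterval iterations between convergence checks (default 200).
#' @param seed integer seed for the symmetry-breaking perturbation.
#' @param perturbAmplitude radial perturbation amplitude as a fraction of
#'   the equal-area sphere radius (default 1e-3; 0 disables).
#' @param rampIterations constraint ramp length; NA (default) means 10
#'   percent of \code{maxIterations}.
#' @param mode "overdamped" (default) or "as-printed".
#' @return a [DynamicsConfig-class].
#' @export
dynamicsConfig <- function(mass = 1e-9, damping = 1e-7, dt = NA_real_,
                           dtSafety = 0.05, maxIterations = 200000L,
                           convergenceTol = 1e-7, checkInterval = 200L,
                           seed = 1L, perturbAmplitude = 1e-3,
                           rampIterations = NA_integer_,
                           mode = c("overdamped", "as-printed")) {
  mode <- match.arg(mode)
  maxIterations <- as.integer(maxIterations)
  if (is.na(rampIterations)) rampIterations <- maxIterations %/% 10L
  new("DynamicsConfig", mass = mass, damping = damping, dt = dt,
      dtSafety = dtSafety, maxIterations = maxIterations,
      convergenceTol = convergenceTol, checkInterval = as.integer(checkInterval),
      seed = as.integer(seed), perturbAmplitude = perturbAmplitude,
      rampIterations = as.integer(rampIterations), mode = mode)
}

# deterministic seeded radial perturbation, restoring the caller's RNG state
.perturbRadially <- function(mesh, amplitude, seed) {
  if (amplitude <= 0) return(mesh)
  v <- mesh@vertices
  ctr <- colMeans(v)
  rel <- sweep(v, 2L, ctr)
  r <- sqrt(rowSums(rel^2))
  Rstar <- sqrt(surfaceArea(mesh) / (4 * pi))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fac <- stats::runif(nrow(v), -1, 1) * amplitude * Rstar
  .withVertices(mesh, v + rel / r * fac)
}

#' Relax a membrane to its minimum free-energy shape
#'
#' Damped descent on the total free energy. A seeded radial perturbation
#' (amplitude \code{perturbAmplitude} times the equal-area sphere radius)
#' breaks the icosahedral symmetry of the starting sphere so that spicule
#' or dimple nucleation is reproducible. The volume, area-difference and
#' total-curvature targets are ramped linearly from the starting mesh's own
#' values to the requested ones over \code{rampIterations} (jumping straight
#' from a sphere to a 0.6 reduced volume can invert the mesh). Iteration
#' stops when every energy component changes by less than
#' \code{convergenceTol} relative between successive checks, or at the
#' iteration budget (then \code{converged} is FALSE).
#'
#' In the default overdamped mode vertices move by (F_i/c) dt and the energy
#' decreases monotonically after the ramp (steps that would raise it are
#' backtracked); the as-printed mode integrates velocities with a
#' multiplicative damping factor. Both reach the same equilibria - c and the
#' particle mass only set the approach speed.
#'
#' @param mesh starting [TriangulatedMembrane-class].
#' @param spectrin a [SpectrinParams-class].
#' @param model an [EnergyModel-class].
#' @param constraints a [ReferenceConstraints-class].
#' @param config a [DynamicsConfig-class] (default [dynamicsConfig()]).
#' @return a [SimulationState-class].
#' @export
relaxMembrane <- function(mesh, spectrin, model, constraints,
                          config = dynamicsConfig()) {
  stopifnot(is(mesh, "TriangulatedMembrane"), is(config, "DynamicsConfig"))
  spectrin <- .expandSpectrin(spectrin, nEdges(mesh))
  nu <- constraints@V0 / ((4 / 3) * pi * sqrt(constraints@A0 / (4 * pi))^3)
  if (nu > 1)
    warning(sprintf("target reduced volume %.3f exceeds 1; the volume constraint cannot be met at the reference area", nu))
  start <- .perturbRadially(mesh, config@perturbAmplitude, config@seed)
  geom0 <- edgeGeometry(start)
  rampStart <- list(
    V0 = enclosedVolume(start) * .UM3,
    dA0 = bilayerAreaDifference(geom0, model@D0 / .UM) * .UM2,
    C0 = totalMembraneCurvature(geom0, model@D0 / .UM) * .UM2)
  res <- .relaxCpp(start@vertices * .UM, start@triangles, start@edges,
                   start@edgeTriangles, start@edgeOpposite,
                   .spectrinList(spectrin), .modelList(model),
                   .constraintListSI(constraints),
                   rampStart, config@rampIterations,
                   config@maxIterations, config@convergenceTol,
                   config@checkInterval,
                   if (config@mode == "overdamped") 0L else 1L,
                   config@damping, config@mass, config@dt, config@dtSafety)
  hist <- as.data.frame(res$history)
  names(hist) <- c("iteration", "stretching", "bending", "surfaceArea",
                   "volume", "areaDifference", "totalCurvature", "total")
  relaxed <- .withVertices(mesh, res$positions / .UM)
  relaxed@metadata$relaxation <- list(seed = config@seed, mode = config@mode,
                                      converged = res$converged,
                                      iterations = res$iterations)
  new("SimulationState",
      membrane = relaxed, velocities = res$velocities,
      iterations = as.integer(res$iterations),
      converged = res$converged, energyHistory = hist)
}

setMethod("show", "SimulationState", function(object) {
  cat(sprintf("SimulationState: %d iterations, %s\n", object@iterations,
              if (object@converged) "converged" else "NOT converged"))
  if (nrow(object@energyHistory)) {
    e <- object@energyHistory[nrow(object@energyHistory), ]
    cat(sprintf("  final total energy: %.6e J\n", e$total))
  }
  show(object@membrane)
})

#' Write the energy history of a run as CSV
#'
#' One row per convergence check: iteration, the six energy components and
#' the total, in joules. The run's primary diagnostic artifact.
#'
#' @param state a [SimulationState-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
energyHistoryCSV <- function(state, path) {
  stopifnot(is(state, "SimulationState"))
  utils::write.csv(state@energyHistory, path, row.names = FALSE)
  invisible(path)
}
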