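# Out-of-plane and constraint energies, and assembly of the total membrane
# free energy. Geometry arrives in micrometres; every energy is returned in
# joules (conversion to SI happens here and nowhere upstream).

.UM <- 1e-6   # metre per micrometre
.UM2 <- 1e-12
.UM3 <- 1e-18

#' Construct an energy model
#'
#' Moduli and constraint coefficients of the membrane free energy, defaulting
#' to the red-cell parameter set used for shape prediction: bending modulus
#' kappa = 2.5e-19 N m, total-area coefficient kA = 1e-3 N/m, local-area
#' coefficient ka = 5e-5 N/m, volume coefficient kv = 100 N/m^2, leaflet
#' area-difference coefficient kad = 7.5e-17 N m, total-curvature coefficient
#' kC = 2.5e-17 N m and monolayer thickness D0 = 2 nm. In the
#' bilayer-coupling regime the area-difference constraint dominates bending
#' (kad/kappa = 300 here, equivalent non-local modulus ~4 kad); a warning is
#' issued if a positive kad is set below 10 kappa.
#'
#' @param kappa bending modulus, N m.
#' @param kA,ka total/local area coefficients, N/m.
#' @param kv volume coefficient, N/m^2.
#' @param kad,kC area-difference and total-curvature coefficients, N m.
#' @param D0 monolayer thickness, m.
#' @return an [EnergyModel-class].
#' @export
energyModel <- function(kappa = 2.5e-19, kA = 1e-3, ka = 5e-5, kv = 100,
                        kad = 7.5e-17, kC = 2.5e-17, D0 = 2e-9) {
  obj <- new("EnergyModel", kappa = kappa, kA = kA, ka = ka, kv = kv,
             kad = kad, kC = kC, D0 = D0)
  if (kad > 0 && kad < 10 * kappa)
    warning(sprintf("kad/kappa = %.3g leaves the bilayer-coupling regime (expect kad >> kappa)",
                    kad / kappa))
  obj
}

#' Construct reference constraints
#'
#' Targets for the constraint energies. The leaflet area difference and total
#' curvature are most naturally quoted as percentages of the reference area
#' (the shape sweeps span dA0/A0 = 0.05-0.30 % and C0/A0 = 0.30-0.90 %);
#' pass them either as absolute areas (\code{dA0}, \code{C0}, square
#' micrometres) or as percentages (\code{dA0Percent}, \code{C0Percent}).
#'
#' @param A0 reference membrane area, square micrometres.
#' @param V0 reference cell volume, cubic micrometres.
#' @param Ak0 per-triangle reference areas, square micrometres.
#' @param dA0,C0 absolute targets, square micrometres.
#' @param dA0Percent,C0Percent targets as percentages of A0.
#' @return a [ReferenceConstraints-class].
#' @examples
#' m <- buildIcosphere(140, 2)
#' referenceConstraints(A0 = 140, V0 = 93.48,
#'   Ak0 = edgeGeometry(m)@triangleAreas,
#'   dA0Percent = 0.12, C0Percent = 0.45)
#' @export
referenceConstraints <- function(A0, V0, Ak0, dA0 = NULL, C0 = NULL,
                                 dA0Percent = NULL, C0Percent = NULL) {
  if (is.null(dA0)) {
    if (is.null(dA0Percent)) stop("give dA0 or dA0Percent")
    dA0 <- dA0Percent / 100 * A0
  }
  if (is.null(C0)) {
    if (is.null(C0Percent)) stop("give C0 or C0Percent")
    C0 <- C0Percent / 100 * A0
  }
  new("ReferenceConstraints", A0 = A0, V0 = V0, Ak0 = Ak0, dA0 = dA0, C0 = C0)
}

#' Discrete bending energy
#'
#' E_Bending = 2 kappa sum_j M_j^2 / dA_j over all edges: the discrete
#' Helfrich energy at zero spontaneous curvature (M_j^2/dA_j is the squared
#' mean curvature times the edge area). Scale-invariant: a sphere of any
#' radius gives 8 pi kappa in the refinement limit.
#'
#' @param geom an [EdgeGeometry-class] (or a mesh).
#' @param kappa bending modulus, N m.
#' @return joules.
#' @export
bendingEnergy <- function(geom, kappa) {
  if (is(geom, "TriangulatedMembrane")) geom <- edgeGeometry(geom)
  stopifnot(is(geom, "EdgeGeometry"))
  if (any(geom@edgeArea <= 0)) stop("degenerate edge area")
  2 * kappa * sum((geom@edgeCurvature * .UM)^2 / (geom@edgeArea * .UM2))
}

#' Surface-area constraint energy
#'
#' Global term kA/2 ((A - A0)/A0)^2 A0 plus the per-triangle local term
#' sum ka/2 ((Ak - Ak0)/Ak0)^2 Ak0; the first penalises total dilation, the
#' second redistribution of area between elements (the bilayer is anchored
#' to the cytoskeleton, so lipid flow over the surface is restricted).
#'
#' @param mesh a [TriangulatedMembrane-class] (or an [EdgeGeometry-class]).
#' @param kA,ka coefficients, N/m.
#' @param constraints a [ReferenceConstraints-class].
#' @return joules.
#' @export
areaEnergy <- function(mesh, kA, ka, constraints) {
  geom <- if (is(mesh, "TriangulatedMembrane")) edgeGeometry(mesh) else mesh
  Ak <- geom@triangleAreas * .UM2
  Ak0 <- constraints@Ak0 * .UM2
  A <- sum(Ak); A0 <- constraints@A0 * .UM2
  0.5 * kA * (A - A0)^2 / A0 + 0.5 * ka * sum((Ak - Ak0)^2 / Ak0)
}

#' Volume constraint energy
#'
#' E_Volume = kv/2 ((V - V0)/V0)^2 V0.
#'
#' @param mesh a [TriangulatedMembrane-class].
#' @param kv coefficient, N/m^2.
#' @param constraints a [ReferenceConstraints-class].
#' @return joules.
#' @export
volumeEnergy <- function(mesh, kv, constraints) {
  V <- enclosedVolume(mesh) * .UM3
  V0 <- constraints@V0 * .UM3
  0.5 * kv * (V - V0)^2 / V0
}

#' Leaflet area-difference constraint energy
#'
#' E = (pi kad / (2 D0^2)) (dA - dA0)^2 / A, the bilayer-coupling penalty on
#' deviations of the leaflet area difference from its reference (equivalent
#' non-local bending modulus ~ 4 kad).
#'
#' @param geom an [EdgeGeometry-class] (or a mesh).
#' @param kad coefficient, N m.
#' @param D0 monolayer thickness, m.
#' @param constraints a [ReferenceConstraints-class].
#' @return joules.
#' @export
areaDifferenceEnergy <- function(geom, kad, D0, constraints) {
  if (is(geom, "TriangulatedMembrane")) geom <- edgeGeometry(geom)
  A <- sum(geom@triangleAreas) * .UM2
  dA <- 2 * (D0 / .UM) * sum(geom@edgeCurvature) * .UM2
  dA0 <- constraints@dA0 * .UM2
  pi * kad / (2 * D0^2) * (dA - dA0)^2 / A
}

#' Total-curvature constraint energy
#'
#' E = (pi kC / (2 D0^2)) (C - C0)^2 / A with C = 2 D0 sum |M_j|: the
#' direction-independent companion of the area-difference constraint that
#' selects a consistent convex/concave arrangement among the many that share
#' one dA.
#'
#' @param geom an [EdgeGeometry-class] (or a mesh).
#' @param kC coefficient, N m.
#' @param D0 monolayer thickness, m.
#' @param constraints a [ReferenceConstraints-class].
#' @return joules.
#' @export
totalCurvatureEnergy <- function(geom, kC, D0, constraints) {
  if (is(geom, "TriangulatedMembrane")) geom <- edgeGeometry(geom)
  A <- sum(geom@triangleAreas) * .UM2
  C <- 2 * (D0 / .UM) * sum(abs(geom@edgeCurvature)) * .UM2
  C0 <- constraints@C0 * .UM2
  pi * kC / (2 * D0^2) * (C - C0)^2 / A
}

#' Total membrane free energy
#'
#' Sum of the six components: stretching, bending, surface area, volume,
#' leaflet area difference and total curvature. Each component is
#' individually non-negative and the total equals their sum exactly.
#'
#' @param mesh a [TriangulatedMembrane-class].
#' @param spectrin a [SpectrinParams-class].
#' @param model an [EnergyModel-class].
#' @param constraints a [ReferenceConstraints-class].
#' @return an [EnergyBreakdown-class].
#' @export
totalEnergy <- function(mesh, spectrin, model, constraints) {
  stopifnot(is(mesh, "TriangulatedMembrane"))
  geom <- edgeGeometry(mesh)
  e <- c(
    stretching = as.numeric(stretchingEnergy(mesh, spectrin)),
    bending = bendingEnergy(geom, model@kappa),
    surfaceArea = areaEnergy(geom, model@kA, model@ka, constraints),
    volume = volumeEnergy(mesh, model@kv, constraints),
    areaDifference = areaDifferenceEnergy(geom, model@kad, model@D0, constraints),
    totalCurvature = totalCurvatureEnergy(geom, model@kC, model@D0, constraints)
  )
  new("EnergyBreakdown",
      stretching = e[["stretching"]], bending = e[["bending"]],
      surfaceArea = e[["surfaceArea"]], volume = e[["volume"]],
      areaDifference = e[["areaDifference"]],
      totalCurvature = e[["totalCurvature"]], total = sum(e))
}

#' @rdname EnergyBreakdown-class
#' @export
setMethod("energyComponents", "EnergyBreakdown", function(object) {
  c(stretching = object@stretching, bending = object@bending,
    surfaceArea = object@surfaceArea, volume = object@volume,
    areaDifference = object@areaDifference,
    totalCurvature = object@totalCurvature, total = object@total)
})

setMethod("show", "EnergyBreakdown", function(object) {
  e <- energyComponents(object)
  cat("EnergyBreakdown (J)\n")
  for (nm in names(e)) cat(sprintf("  %-15s %.6e\n", nm, e[[nm]]))
})

setMethod("show", "EnergyModel", function(object) {
  cat("EnergyModel\n")
  cat(sprintf("  kappa = %.3g N m, kA = %.3g N/m, ka = %.3g N/m, kv = %.3g N/m^2\n",
              object@kappa, object@kA, object@ka, object@kv))
  cat(sprintf("  kad = %.3g N m, kC = %.3g N m, D0 = %.3g m (kad/kappa = %.3g)\n",
              object@kad, object@kC, object@D0,
              if (object@kappa > 0) object@kad / object@kappa else NA))
})

setMethod("show", "ReferenceConstraints", function(object) {
  cat("ReferenceConstraints\n")
  cat(sprintf("  A0 = %.4g um^2, V0 = %.4g um^3 (nu = %.3f)\n",
              object@A0, object@V0,
              object@V0 / ((4 / 3) * pi * (sqrt(object@A0 / (4 * pi)))^3)))
  cat(sprintf("  dA0 = %.4g um^2 (%.3g%% of A0), C0 = %.4g um^2 (%.3g%% of A0)\n",
              object@dA0, 100 * object@dA0 / object@A0,
              object@C0, 100 * object@C0 / object@A0))
  cat(sprintf("  %d per-triangle reference areas, sum = %.4g um^2\n",
              length(object@Ak0), sum(object@Ak0)))
})
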