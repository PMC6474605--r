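#' @import methods
#' @importFrom stats setNames
#' @importFrom Rcpp sourceCpp
#' @useDynLib rbcshape, .registration = TRUE
NULL

#' Closed triangulated membrane surface
#'
#' The discretised red-blood-cell membrane: a closed, manifold, genus-0
#' triangle mesh with outward-oriented faces and precomputed edge topology.
#' Vertex coordinates are in micrometres. Triangle rows list vertex indices
#' counter-clockwise as seen from outside the cell; \code{edges} holds each
#' unique edge once with its smaller index first; \code{edgeTriangles} gives,
#' for every edge (a, b) with a < b, the triangle containing the directed
#' edge a->b first (T1) and the one containing b->a second (T2);
#' \code{edgeOpposite} gives the remaining vertex of T1 and T2.
#'
#' Construct with [buildMembrane()], [buildIcosahedron()], [buildIcosphere()]
#' or [buildEllipsoid()]; do not fill slots by hand.
#'
#' @slot vertices numeric matrix (nV x 3), micrometres.
#' @slot triangles integer matrix (nT x 3), 1-based vertex indices, ccw
#'   from outside.
#' @slot edges integer matrix (nE x 2), unique undirected edges, a < b.
#' @slot edgeTriangles integer matrix (nE x 2), incident triangles (T1, T2).
#' @slot edgeOpposite integer matrix (nE x 2), opposite vertices in T1, T2.
#' @slot metadata list; construction parameters (e.g. subdivision level,
#'   sphere radius).
#' @export
setClass("TriangulatedMembrane",
  representation(
    vertices      = "matrix",
    triangles     = "matrix",
    edges         = "matrix",
    edgeTriangles = "matrix",
    edgeOpposite  = "matrix",
    metadata      = "list"
  )
)

setValidity("TriangulatedMembrane", function(object) {
  v <- object@vertices; tr <- object@triangles; ed <- object@edges
  msg <- character()
  if (ncol(v) != 3 || !is.numeric(v)) msg <- c(msg, "vertices must be an nV x 3 numeric matrix")
  if (ncol(tr) != 3) msg <- c(msg, "triangles must be an nT x 3 matrix")
  if (any(!is.finite(v))) msg <- c(msg, "vertex coordinates must be finite")
  nV <- nrow(v); nT <- nrow(tr); nE <- nrow(ed)
  if (nV - nE + nT != 2L)
    msg <- c(msg, sprintf("Euler characteristic V - E + F = %d, expected 2 (genus-0 closed surface)",
                          nV - nE + nT))
  if (2L * nE != 3L * nT)
    msg <- c(msg, "edge/triangle counts inconsistent with a closed triangle mesh (2E != 3F)")
  if (nrow(object@edgeTriangles) != nE || nrow(object@edgeOpposite) != nE)
    msg <- c(msg, "edge maps must have one row per edge")
  if (length(msg)) msg else TRUE
})

#' Triangulation quality summary
#'
#' Edge-length statistics (population standard deviation) and the vertex
#' valence distribution of a [TriangulatedMembrane-class].
#'
#' @slot edgeLengthMean mean edge length, micrometres.
#' @slot edgeLengthSD population standard deviation of edge lengths,
#'   micrometres.
#' @slot lengthRatio \code{edgeLengthSD / edgeLengthMean}, dimensionless.
#' @slot valenceHistogram named integer vector: vertex count per valence.
#' @slot valenceFractions named numeric vector summing to 1.
#' @export
setClass("MeshQuality",
  representation(
    edgeLengthMean   = "numeric",
    edgeLengthSD     = "numeric",
    lengthRatio      = "numeric",
    valenceHistogram = "integer",
    valenceFractions = "numeric"
  )
)

#' Per-edge discrete geometry of a membrane mesh
#'
#' Holds, for every unique edge j: its length l_j, the signed dihedral angle
#' theta_j between the outward normals of the two incident triangles
#' (positive where the surface is locally convex as seen from outside,
#' negative in concave invaginations), the edge curvature
#' M_j = l_j * theta_j / 2, and the edge-associated area
#' dA_j = (A_T1 + A_T2) / 3; plus per-triangle areas and unit normals.
#' The edge areas partition the surface: sum(dA_j) equals the total area
#' exactly.
#'
#' @slot lengths numeric, per edge, micrometres.
#' @slot dihedrals numeric, per edge, radians, signed.
#' @slot edgeCurvature numeric, M_j, micrometres.
#' @slot edgeArea numeric, dA_j, square micrometres.
#' @slot triangleAreas numeric, per triangle, square micrometres.
#' @slot triangleNormals numeric matrix (nT x 3), outward unit normals.
#' @export
setClass("EdgeGeometry",
  representation(
    lengths         = "numeric",
    dihedrals       = "numeric",
    edgeCurvature   = "numeric",
    edgeArea        = "numeric",
    triangleAreas   = "numeric",
    triangleNormals = "matrix"
  )
)

#' Shape morphometry of a membrane mesh
#'
#' All scalar shape descriptors used to characterise and compare cell
#' shapes: surface area A, enclosed volume V, reduced volume
#' nu = V / ((4/3) pi R*^3) with R* = sqrt(A / 4 pi) the equal-area sphere
#' radius, bilayer-leaflet area difference dA = 2 D0 sum(M_j), total membrane
#' curvature C = 2 D0 sum(|M_j|), sorted principal-axis extents
#' H1 <= H2 <= H3, normalised length Hx = H3 / R*, normalised thickness
#' Hz = H1 / R*, shape factor SF = H1 / sqrt(H2 H3), and the per-vertex
#' curvature field CV (1/micrometre; positive on convex regions such as
#' spicules, negative in dimples).
#'
#' @slot area square micrometres.
#' @slot volume cubic micrometres.
#' @slot reducedVolume dimensionless, in (0, 1] up to discretisation error.
#' @slot areaDifference square micrometres (signed).
#' @slot totalCurvature square micrometres; always >= |areaDifference|.
#' @slot extents numeric length 3, H1 <= H2 <= H3, micrometres.
#' @slot Hx,Hz,SF dimensionless descriptors.
#' @slot Rstar equal-area sphere radius, micrometres.
#' @slot D0 monolayer thickness used, micrometres.
#' @slot vertexCurvature numeric, per vertex, 1/micrometre.
#' @export
setClass("ShapeMetrics",
  representation(
    area            = "numeric",
    volume          = "numeric",
    reducedVolume   = "numeric",
    areaDifference  = "numeric",
    totalCurvature  = "numeric",
    extents         = "numeric",
    Hx              = "numeric",
    Hz              = "numeric",
    SF              = "numeric",
    Rstar           = "numeric",
    D0              = "numeric",
    vertexCurvature = "numeric"
  )
)

setValidity("ShapeMetrics", function(object) {
  msg <- character()
  if (length(object@extents) != 3L) msg <- c(msg, "extents must have length 3")
  if (is.unsorted(object@extents)) msg <- c(msg, "extents must be sorted ascending (H1 <= H2 <= H3)")
  if (object@totalCurvature < abs(object@areaDifference) - 1e-9 * object@totalCurvature)
    msg <- c(msg, "total curvature must dominate |area difference|")
  if (length(msg)) msg else TRUE
})

#' Spectrin network (in-plane) elastic parameters
#'
#' Worm-like-chain attraction plus power-law repulsion per spectrin link.
#' Link rest lengths l0 and maximum extensions lmax = l0 / x0 are stored per
#' edge (the cytoskeletal reference state need not be uniform); the
#' persistence length p is global, and the repulsion coefficient kp is set
#' per edge by the condition of zero net link force at l0. All length slots
#' are SI (metres); energies evaluate in joules.
#'
#' @slot l0 rest length per edge, metres.
#' @slot lmax maximum extension per edge, metres (l0 / x0).
#' @slot p persistence length, metres.
#' @slot kp power-law coefficient per edge, N m^(m+1).
#' @slot m repulsion exponent, dimensionless, > 0.
#' @slot x0 equilibrium extension ratio l0/lmax, in (0, 1).
#' @slot kBT thermal energy, joules.
#' @slot mu0 membrane shear modulus the calibration reproduces, N/m.
#' @slot sqrt3 logical; TRUE uses the coarse-graining literature form of the
#'   shear-modulus relation (with its sqrt(3) prefactors), FALSE the
#'   strict-as-printed variant.
#' @export
setClass("SpectrinParams",
  representation(
    l0    = "numeric",
    lmax  = "numeric",
    p     = "numeric",
    kp    = "numeric",
    m     = "numeric",
    x0    = "numeric",
    kBT   = "numeric",
    mu0   = "numeric",
    sqrt3 = "logical"
  )
)

setValidity("SpectrinParams", function(object) {
  msg <- character()
  if (any(object@l0 <= 0)) msg <- c(msg, "l0 must be positive")
  if (object@x0 <= 0 || object@x0 >= 1) msg <- c(msg, "x0 must lie strictly in (0, 1)")
  if (any(object@l0 >= object@lmax)) msg <- c(msg, "l0 must be strictly below lmax")
  if (object@p <= 0 || any(object@kp <= 0) || object@m <= 0)
    msg <- c(msg, "p, kp and m must be positive")
  if (length(msg)) msg else TRUE
})

#' Membrane energy model coefficients
#'
#' Moduli and constraint coefficients of the total free energy: bending
#' modulus kappa, total- and local-area coefficients kA and ka, volume
#' coefficient kv, bilayer-leaflet-area-difference coefficient kad, total
#' membrane curvature coefficient kC, and monolayer thickness D0. All SI.
#' In the bilayer-coupling regime kad dominates kappa (defaults: kad/kappa
#' = 300); the constructor [energyModel()] warns when kad > 0 leaves that
#' regime.
#'
#' @slot kappa bending modulus, N m.
#' @slot kA total-area coefficient, N/m.
#' @slot ka local-area coefficient, N/m.
#' @slot kv volume coefficient, N/m^2.
#' @slot kad area-difference coefficient, N m.
#' @slot kC total-curvature coefficient, N m.
#' @slot D0 monolayer thickness, m.
#' @export
setClass("EnergyModel",
  representation(
    kappa = "numeric", kA = "numeric", ka = "numeric", kv = "numeric",
    kad = "numeric", kC = "numeric", D0 = "numeric"
  )
)

setValidity("EnergyModel", function(object) {
  msg <- character()
  vals <- c(object@kappa, object@kA, object@ka, object@kv, object@kad, object@kC)
  if (any(vals < 0)) msg <- c(msg, "all coefficients must be non-negative")
  if (object@D0 <= 0) msg <- c(msg, "D0 must be positive")
  if (length(msg)) msg else TRUE
})

#' Reference constraints for shape relaxation
#'
#' Target values the constraint energies penalise deviations from:
#' reference membrane area A0, cell volume V0, per-triangle areas Ak0,
#' bilayer-leaflet area difference dA0 and total membrane curvature C0.
#' Geometry units (micrometres-based) throughout; [referenceConstraints()]
#' accepts dA0 and C0 as percentages of A0, the convention used to
#' parameterise shape sweeps.
#'
#' @slot A0 square micrometres.
#' @slot V0 cubic micrometres.
#' @slot Ak0 numeric, per triangle, square micrometres.
#' @slot dA0 square micrometres.
#' @slot C0 square micrometres.
#' @export
setClass("ReferenceConstraints",
  representation(
    A0 = "numeric", V0 = "numeric", Ak0 = "numeric",
    dA0 = "numeric", C0 = "numeric"
  )
)

setValidity("ReferenceConstraints", function(object) {
  msg <- character()
  if (object@A0 <= 0 || object@V0 <= 0) msg <- c(msg, "A0 and V0 must be positive")
  if (any(object@Ak0 <= 0)) msg <- c(msg, "per-triangle reference areas must be positive")
  if (length(msg)) msg else TRUE
})

#' Free-energy breakdown
#'
#' The six components of the membrane free energy (stretching, bending,
#' surface area, volume, area difference, total curvature) and their sum,
#' all in joules. \code{total} is exactly the sum of the components.
#'
#' @slot stretching,bending,surfaceArea,volume,areaDifference,totalCurvature
#'   component energies, joules.
#' @slot total sum of the six components, joules.
#' @export
setClass("EnergyBreakdown",
  representation(
    stretching = "numeric", bending = "numeric", surfaceArea = "numeric",
    volume = "numeric", areaDifference = "numeric", totalCurvature = "numeric",
    total = "numeric"
  )
)

#' Relaxation dynamics configuration
#'
#' Controls the damped descent toward the minimum free-energy shape.
#' The default mode \code{"overdamped"} moves each vertex by (F_i / c) dt
#' (first-order relaxation; the equilibrium does not depend on c or the
#' particle mass). Mode \code{"as-printed"} integrates velocities with a
#' multiplicative damping factor c and acceleration F_i / m_i. The time step
#' is chosen adaptively when \code{dt} is NA: displacement per step is capped
#' at \code{dtSafety} times the minimum edge length, with backtracking when a
#' step would raise the energy (after the constraint ramp). Convergence is
#' declared when every energy component changes by less than
#' \code{convergenceTol} relative between successive checks (components below
#' 1e-25 J or below a millionth of the total are deemed converged).
#'
#' @slot mass particle mass, kg (as-printed mode only).
#' @slot damping viscosity c: N s/m in overdamped mode, dimensionless
#'   multiplicative factor in as-printed mode.
#' @slot dt time step, seconds; NA for adaptive.
#' @slot dtSafety fractional displacement cap per step (default 0.05).
#' @slot maxIterations iteration budget.
#' @slot convergenceTol relative per-component energy tolerance.
#' @slot checkInterval iterations between convergence checks.
#' @slot seed integer seed for the symmetry-breaking radial perturbation.
#' @slot perturbAmplitude amplitude of that perturbation as a fraction of the
#'   equal-area sphere radius (default 1e-3; 0 disables).
#' @slot rampIterations iterations over which V0, dA0 and C0 are interpolated
#'   linearly from the starting mesh's own values to their targets.
#' @slot mode "overdamped" or "as-printed".
#' @export
setClass("DynamicsConfig",
  representation(
    mass = "numeric", damping = "numeric", dt = "numeric", dtSafety = "numeric",
    maxIterations = "integer", convergenceTol = "numeric",
    checkInterval = "integer", seed = "integer", perturbAmplitude = "numeric",
    rampIterations = "integer", mode = "character"
  )
)

setValidity("DynamicsConfig", function(object) {
  msg <- character()
  if (!is.na(object@dt) && object@dt <= 0) msg <- c(msg, "dt must be positive (or NA for adaptive)")
  if (object@mass <= 0) msg <- c(msg, "mass must be positive")
  if (object@damping < 0) msg <- c(msg, "damping must be non-negative")
  if (object@convergenceTol <= 0) msg <- c(msg, "convergenceTol must be positive")
  if (!object@mode %in% c("overdamped", "as-printed"))
    msg <- c(msg, "mode must be 'overdamped' or 'as-printed'")
  if (length(msg)) msg else TRUE
})

#' State of a relaxation run
#'
#' @slot membrane the relaxed (or current) [TriangulatedMembrane-class].
#' @slot velocities numeric matrix (nV x 3), m/s.
#' @slot iterations iterations executed.
#' @slot converged logical flag.
#' @slot energyHistory data.frame: iteration, the six energy components and
#'   the total (joules), one row per convergence check.
#' @export
setClass("SimulationState",
  representation(
    membrane = "TriangulatedMembrane", velocities = "matrix",
    iterations = "integer", converged = "logical",
    energyHistory = "data.frame"
  )
)

#' Stress-free cytoskeletal reference state
#'
#' The relaxed cytoskeleton-only geometry (an oblate spheroid at reduced
#' volume nuCyto) from which per-link rest lengths l0 and per-triangle
#' reference areas are read. Generated by [generateReference()].
#'
#' @slot membrane converged reference mesh.
#' @slot l0 rest length per edge, micrometres.
#' @slot Ak0 reference area per triangle, square micrometres.
#' @slot nuCyto requested reduced volume.
#' @slot A0 reference surface area, square micrometres.
#' @slot V0 reference volume, cubic micrometres.
#' @export
setClass("CytoskeletonReference",
  representation(
    membrane = "TriangulatedMembrane", l0 = "numeric", Ak0 = "numeric",
    nuCyto = "numeric", A0 = "numeric", V0 = "numeric"
  )
)

setValidity("CytoskeletonReference", function(object) {
  msg <- character()
  if (any(object@l0 <= 0)) msg <- c(msg, "l0 must be positive")
  if (object@nuCyto <= 0 || object@nuCyto > 1) msg <- c(msg, "nuCyto must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
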