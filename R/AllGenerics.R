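#' @rdname TriangulatedMembrane-class
#' @param x,object a \code{TriangulatedMembrane}.
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' @rdname TriangulatedMembrane-class
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))

#' @rdname TriangulatedMembrane-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname TriangulatedMembrane-class
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))

#' @rdname TriangulatedMembrane-class
#' @export
setGeneric("nTriangles", function(x) standardGeneric("nTriangles"))

#' @rdname TriangulatedMembrane-class
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' Surface area of a closed mesh
#'
#' Sum of the planar triangle areas, in square micrometres.
#' @param x a [TriangulatedMembrane-class].
#' @return numeric scalar, square micrometres.
#' @export
setGeneric("surfaceArea", function(x) standardGeneric("surfaceArea"))

#' Enclosed volume of a closed mesh
#'
#' Signed sum of origin tetrahedra (divergence theorem); positive for
#' outward orientation and invariant under translation.
#' @param x a [TriangulatedMembrane-class].
#' @return numeric scalar, cubic micrometres.
#' @export
setGeneric("enclosedVolume", function(x) standardGeneric("enclosedVolume"))

#' @rdname EnergyBreakdown-class
#' @param object an \code{EnergyBreakdown}.
#' @return \code{energyComponents} returns a named numeric vector of the six
#'   components plus the total, joules.
#' @export
setGeneric("energyComponents", function(object) standardGeneric("energyComponents"))
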