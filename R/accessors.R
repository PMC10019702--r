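#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers: `weightMatrix`
#' returns a connectome's coupling matrix, `regionLabels` its region names,
#' `nRegions` its dimension; `fcValues` and `fcSpace` expose a
#' [FCMatrix-class]'s matrix and value space; `gridPoints` and `gridSteps`
#' expose a [ParameterGrid-class]; `paramVector` flattens a
#' [ModelParameters-class] to a named numeric vector `(A, G, F, M, beta)`.
#'
#' @param x object of the matching class.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @rdname accessors
#' @export
setGeneric("fcValues", function(x) standardGeneric("fcValues"))
#' @rdname accessors
#' @export
setGeneric("fcSpace", function(x) standardGeneric("fcSpace"))
#' @rdname accessors
#' @export
setGeneric("gridPoints", function(x) standardGeneric("gridPoints"))
#' @rdname accessors
#' @export
setGeneric("gridSteps", function(x) standardGeneric("gridSteps"))
#' @rdname accessors
#' @export
setGeneric("paramVector", function(x) standardGeneric("paramVector"))

#' @rdname accessors
#' @export
setMethod("weightMatrix", "StructuralConnectome", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("regionLabels", "StructuralConnectome", function(x) x@regionLabels)
#' @rdname accessors
#' @export
setMethod("nRegions", "StructuralConnectome", function(x) nrow(x@weights))
#' @rdname accessors
#' @export
setMethod("fcValues", "FCMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("fcSpace", "FCMatrix", function(x) x@space)
#' @rdname accessors
#' @export
setMethod("gridPoints", "ParameterGrid", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("gridSteps", "ParameterGrid", function(x) x@steps)
#' @rdname accessors
#' @export
setMethod("paramVector", "ModelParameters", function(x)
  c(A = x@A, G = x@G, F = x@F, M = x@M, beta = x@beta))

setMethod("show", "StructuralConnectome", function(object) {
  cat(sprintf("StructuralConnectome: %d regions, %s\n",
              nrow(object@weights),
              if (object@normalized) "row-normalized" else "unnormalized"))
  dens <- mean(object@weights[row(object@weights) != col(object@weights)] > 0)
  cat(sprintf("  edge density %.2f; first regions: %s ...\n", dens,
              paste(utils::head(object@regionLabels, 3), collapse = ", ")))
})

setMethod("show", "ModelParameters", function(object) {
  cat(sprintf(
    "ModelParameters: A=%.3f G=%.3f F=%.2f M=%.2f beta=%.3f\n",
    object@A, object@G, object@F, object@M, object@beta))
})

setMethod("show", "StateTrajectory", function(object) {
  cat(sprintf("StateTrajectory: %d regions x %d samples (every %.1f s)\n",
              nrow(object@z), ncol(object@z), object@sampleInterval))
})

setMethod("show", "FCMatrix", function(object) {
  cat(sprintf("FCMatrix (%s): %d x %d, provenance: %s\n", object@space,
              nrow(object@values), ncol(object@values),
              object@provenance$type))
})

setMethod("show", "ParameterGrid", function(object) {
  cat(sprintf("ParameterGrid: %d points (steps A=%g G=%g F=%g M=%g)\n",
              nrow(object@points), object@steps["A"], object@steps["G"],
              object@steps["F"], object@steps["M"]))
})

setMethod("show", "GridSimBank", function(object) {
  cat(sprintf("GridSimBank: %d simulated grid points, %d regions\n",
              length(object@fcs),
              if (length(object@fcs)) nrow(object@fcs[[1]]@values) else 0L))
})

setMethod("show", "SubtypeSolution", function(object) {
  cat("SubtypeSolution (DEP1 = higher-metastability mode)\n")
  p1 <- paramVector(object@paramsDep1); p2 <- paramVector(object@paramsDep2)
  cat(sprintf("  DEP1: A=%+.3f G=%.3f F=%.2f M=%.2f  (%d iterations)\n",
              p1["A"], p1["G"], p1["F"], p1["M"], object@modeCounts[1]))
  cat(sprintf("  DEP2: A=%+.3f G=%.3f F=%.2f M=%.2f  (%d iterations)\n",
              p2["A"], p2["G"], p2["F"], p2["M"], object@modeCounts[2]))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d subjects (%d with simulated FC)\n",
              nrow(object@cohort), length(object@fcs)))
})
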