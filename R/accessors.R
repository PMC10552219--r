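#' Accessors for spatialTME containers
#'
#' `cellData()` returns the per-cell data.frame, `markerNames()` the marker
#' columns, `sampleIds()` the unique sample identifiers, `gValues()` and
#' `gRadii()` the components of a [GFunctionCurve-class].
#'
#' @param x a [CellTable-class] or [GFunctionCurve-class] object.
#' @return `cellData`: data.frame; `markerNames`, `sampleIds`: character;
#'   `gValues`, `gRadii`: numeric.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cellData", function(x) standardGeneric("cellData"))

#' @rdname accessors
#' @export
setMethod("cellData", "CellTable", function(x) x@cells)

#' @rdname accessors
#' @export
setGeneric("markerNames", function(x) standardGeneric("markerNames"))

#' @rdname accessors
#' @export
setMethod("markerNames", "CellTable", function(x) x@markers)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "CellTable", function(x) unique(x@cells$sample_id))

#' @rdname accessors
#' @export
setGeneric("gValues", function(x) standardGeneric("gValues"))

#' @rdname accessors
#' @export
setMethod("gValues", "GFunctionCurve", function(x) x@g)

#' @rdname accessors
#' @export
setGeneric("gRadii", function(x) standardGeneric("gRadii"))

#' @rdname accessors
#' @export
setMethod("gRadii", "GFunctionCurve", function(x) x@radii)

#' Subset a CellTable to one sample
#'
#' @param x a [CellTable-class].
#' @param sample sample identifier.
#' @return A [CellTable-class] holding only that sample's cells.
#' @export
subsetSample <- function(x, sample) {
    stopifnot(methods::is(x, "CellTable"))
    df <- x@cells[x@cells$sample_id == sample, , drop = FALSE]
    methods::new("CellTable", cells = df, markers = x@markers)
}
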