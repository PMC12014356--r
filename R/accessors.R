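#' Accessors for CnvCallSet and BreakpointMatrix
#'
#' `cnvCalls()` returns the call `GRanges`, `sampleTable()` the sample
#' `DataFrame`, `genomeBuild()` the build tag, `nSamples()` the number of
#' samples, and `nCalls()` the number of calls. For a
#' [BreakpointMatrix-class], `altMatrix()`/`missingMatrix()` return the
#' sparse indicator matrices, `breakpoints()` the breakpoint `GRanges`, and
#' `bpModel()` the encoding model.
#'
#' @param x a `CnvCallSet` or `BreakpointMatrix`.
#' @param value replacement value.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cnvCalls", function(x) standardGeneric("cnvCalls"))
#' @rdname accessors
#' @export
setMethod("cnvCalls", "CnvCallSet", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("sampleTable", function(x) standardGeneric("sampleTable"))
#' @rdname accessors
#' @export
setMethod("sampleTable", "CnvCallSet", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("genomeBuild", function(x) standardGeneric("genomeBuild"))
#' @rdname accessors
#' @export
setMethod("genomeBuild", "CnvCallSet", function(x) x@genome)

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname accessors
#' @export
setMethod("nSamples", "CnvCallSet", function(x) nrow(x@samples))
#' @rdname accessors
#' @export
setMethod("nSamples", "BreakpointMatrix", function(x) nrow(x@alt))

#' @rdname accessors
#' @export
setGeneric("nCalls", function(x) standardGeneric("nCalls"))
#' @rdname accessors
#' @export
setMethod("nCalls", "CnvCallSet", function(x) length(x@calls))

#' @rdname accessors
#' @export
setGeneric("altMatrix", function(x) standardGeneric("altMatrix"))
#' @rdname accessors
#' @export
setMethod("altMatrix", "BreakpointMatrix", function(x) x@alt)

#' @rdname accessors
#' @export
setGeneric("missingMatrix", function(x) standardGeneric("missingMatrix"))
#' @rdname accessors
#' @export
setMethod("missingMatrix", "BreakpointMatrix", function(x) x@missing)

#' @rdname accessors
#' @export
setGeneric("breakpoints", function(x) standardGeneric("breakpoints"))
#' @rdname accessors
#' @export
setMethod("breakpoints", "BreakpointMatrix", function(x) x@breakpoints)

#' @rdname accessors
#' @export
setGeneric("bpModel", function(x) standardGeneric("bpModel"))
#' @rdname accessors
#' @export
setMethod("bpModel", "BreakpointMatrix", function(x) x@model)

# replace the calls of a CnvCallSet, keeping samples/genome (internal)
.replaceCalls <- function(x, calls) {
  initialize(x, calls = calls)
}
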