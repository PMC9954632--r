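#' Accessors for shapeMR objects
#'
#' Small accessor generics so user code never reaches into slots:
#' `theta()` returns the causal log-OR, `oddsRatio()` the exponentiated
#' estimate, `stdError()` its standard error, `pValue()` the two-sided
#' p-value, `nVariants()` the instrument count, `qPvalue()` the Cochran-Q
#' p-value, `i2GX()` the NOME statistic, `instruments()` the per-variant
#' table of a panel or harmonized set, and `dropLog()` the rejection or
#' drop log.
#'
#' @param x a shapeMR object.
#' @return the corresponding scalar, vector or `data.frame`.
#' @name accessors
#' @aliases theta oddsRatio stdError pValue nVariants qPvalue i2GX
#'   instruments dropLog exposureName outcomeName
NULL

#' @rdname accessors
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))
#' @rdname accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))
#' @rdname accessors
#' @export
setGeneric("stdError", function(x) standardGeneric("stdError"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @rdname accessors
#' @export
setGeneric("qPvalue", function(x) standardGeneric("qPvalue"))
#' @rdname accessors
#' @export
setGeneric("i2GX", function(x) standardGeneric("i2GX"))
#' @rdname accessors
#' @export
setGeneric("instruments", function(x) standardGeneric("instruments"))
#' @rdname accessors
#' @export
setGeneric("dropLog", function(x) standardGeneric("dropLog"))
#' @rdname accessors
#' @export
setGeneric("exposureName", function(x) standardGeneric("exposureName"))
#' @rdname accessors
#' @export
setGeneric("outcomeName", function(x) standardGeneric("outcomeName"))

#' @rdname accessors
setMethod("theta", "MREstimate", function(x) x@theta)
#' @rdname accessors
setMethod("oddsRatio", "MREstimate", function(x) x@oddsRatio)
#' @rdname accessors
setMethod("stdError", "MREstimate", function(x) x@se)
#' @rdname accessors
setMethod("pValue", "MREstimate", function(x) x@pvalue)
#' @rdname accessors
setMethod("nVariants", "MREstimate", function(x) x@nVariants)

#' @rdname accessors
setMethod("qPvalue", "PleiotropyDiagnostics", function(x) x@qPvalue)
#' @rdname accessors
setMethod("i2GX", "PleiotropyDiagnostics", function(x) x@i2GX)

#' @rdname accessors
setMethod("instruments", "MRPanel", function(x) x@data)
#' @rdname accessors
setMethod("instruments", "MRHarmonized", function(x) x@data)
#' @rdname accessors
setMethod("dropLog", "MRPanel", function(x) x@rejected)
#' @rdname accessors
setMethod("dropLog", "MRHarmonized", function(x) x@dropped)
#' @rdname accessors
setMethod("exposureName", "MRPanel", function(x) x@exposureName)
#' @rdname accessors
setMethod("exposureName", "MRHarmonized", function(x) x@exposureName)
#' @rdname accessors
setMethod("outcomeName", "MRHarmonized", function(x) x@outcomeName)

#' @rdname accessors
#' @export
setMethod("length", "MRPanel", function(x) nrow(x@data))
#' @rdname accessors
#' @export
setMethod("length", "MRHarmonized", function(x) nrow(x@data))

#' Confidence interval of an MR estimate
#'
#' @param object an [MREstimate-class].
#' @param parm ignored.
#' @param level ignored; intervals are the stored 95% bounds.
#' @param ... ignored.
#' @return numeric vector `c(lower, upper)` on the log-OR scale.
#' @export
setMethod("confint", "MREstimate", function(object, parm, level = 0.95, ...) {
  c(lower = object@ciLower, upper = object@ciUpper)
})
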