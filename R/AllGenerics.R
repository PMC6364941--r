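#' @name nmrsigex-accessors
#' @title Accessors for nmrsigex classes
#' @description Small accessor generics for the package's S4 classes.
#' @param object an object of the documented class.
#' @param x an object of the documented class.
NULL

#' @rdname nmrsigex-accessors
#' @export
setGeneric("ppm", function(object) standardGeneric("ppm"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("fieldMHz", function(object) standardGeneric("fieldMHz"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("exclusionMask", function(object) standardGeneric("exclusionMask"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("processingLog", function(object) standardGeneric("processingLog"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("multiplets", function(object) standardGeneric("multiplets"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("metaboliteNames", function(object, ...) standardGeneric("metaboliteNames"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("lipidResonances", function(object) standardGeneric("lipidResonances"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("cohortLabels", function(object) standardGeneric("cohortLabels"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("concentrations", function(object) standardGeneric("concentrations"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("lipidLevels", function(object) standardGeneric("lipidLevels"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("shiftJitter", function(object) standardGeneric("shiftJitter"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("coefficients95", function(object) standardGeneric("coefficients95"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("metaboliteFit", function(object) standardGeneric("metaboliteFit"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("residualFit", function(object) standardGeneric("residualFit"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("fitSum", function(object) standardGeneric("fitSum"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("sampleLabels", function(object) standardGeneric("sampleLabels"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("cvIterations", function(object) standardGeneric("cvIterations"))
#' @rdname nmrsigex-accessors
#' @export
setGeneric("cvProbabilities", function(object) standardGeneric("cvProbabilities"))
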