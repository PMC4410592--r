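#' @rdname MethylationExperiment
#' @param x,object a `MethylationExperiment`.
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname MethylationExperiment
#' @export
setGeneric("detectionP", function(x) standardGeneric("detectionP"))

#' @rdname MethylationExperiment
#' @export
setGeneric("mValues", function(x) standardGeneric("mValues"))

#' @rdname MethylationExperiment
#' @export
setGeneric("probeManifest", function(x) standardGeneric("probeManifest"))

#' @rdname MethylationExperiment
#' @export
setGeneric("sampleRoles", function(x) standardGeneric("sampleRoles"))

#' @rdname MethylationExperiment
#' @export
setGeneric("caseSample", function(x) standardGeneric("caseSample"))

#' @rdname MethylationExperiment
#' @export
setGeneric("controlSamples", function(x) standardGeneric("controlSamples"))

#' @rdname SingleCaseTest-class
#' @param x a `SingleCaseTest`.
#' @export
setGeneric("tStatistic", function(x) standardGeneric("tStatistic"))

#' @rdname SingleCaseTest-class
#' @export
setGeneric("degreesOfFreedom", function(x) standardGeneric("degreesOfFreedom"))

#' @rdname SingleCaseTest-class
#' @param tail which tail probability to return.
#' @export
setGeneric("pValue", function(x, tail = c("lower", "upper", "two.sided"))
    standardGeneric("pValue"))
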