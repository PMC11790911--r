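#' @rdname SeasonalExperiment
#' @param x,object a \code{SeasonalExperiment}, \code{OscillationSet} or
#'   \code{CoOscNetwork} as appropriate.
#' @export
setGeneric("featureClass", function(x) standardGeneric("featureClass"))

#' @rdname SeasonalExperiment
#' @export
setGeneric("sampleDates", function(x) standardGeneric("sampleDates"))

#' @rdname SeasonalExperiment
#' @export
setGeneric("dayOfYear", function(x) standardGeneric("dayOfYear"))

#' @rdname SeasonalExperiment
#' @export
setGeneric("yearIndex", function(x) standardGeneric("yearIndex"))

#' @rdname SeasonalExperiment
#' @export
setGeneric("envCovariates", function(x) standardGeneric("envCovariates"))

#' @rdname OscillationSet
#' @export
setGeneric("consensusOscillation",
           function(x) standardGeneric("consensusOscillation"))

#' @rdname OscillationSet
#' @export
setGeneric("annualOscillators",
           function(x) standardGeneric("annualOscillators"))

#' @rdname OscillationSet
#' @export
setGeneric("peakDays", function(x) standardGeneric("peakDays"))

#' @rdname OscillationSet
#' @export
setGeneric("peakCounts", function(x) standardGeneric("peakCounts"))

#' @rdname OscillationSet
#' @export
setGeneric("reconstructedSignals",
           function(x) standardGeneric("reconstructedSignals"))

#' @rdname CoOscNetwork
#' @export
setGeneric("networkGraph", function(x) standardGeneric("networkGraph"))

#' @rdname CoOscNetwork
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))

#' @rdname CoOscNetwork
#' @export
setGeneric("moduleSizes", function(x) standardGeneric("moduleSizes"))
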