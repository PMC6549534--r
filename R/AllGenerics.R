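#' @describeIn CascadeReport the per-gene filter-trail table.
#' @param object a \code{CascadeReport} (or \code{SynthData}) object.
#' @export
setGeneric("cascadeTable", function(object) standardGeneric("cascadeTable"))

#' @describeIn CascadeReport named survivor counts along the funnel.
#' @export
setGeneric("filterCounts", function(object) standardGeneric("filterCounts"))

#' @describeIn CascadeReport gene ids surviving every filter.
#' @export
setGeneric("cascadeSurvivors",
           function(object) standardGeneric("cascadeSurvivors"))

#' @describeIn SynthData the planted ground-truth table.
#' @export
setGeneric("truthTable", function(object) standardGeneric("truthTable"))

#' @describeIn SynthData the promoter sequences.
#' @export
setGeneric("promoterSet", function(object) standardGeneric("promoterSet"))

#' @describeIn SynthData the generating configuration.
#' @export
setGeneric("generatorConfig",
           function(object) standardGeneric("generatorConfig"))

setMethod("cascadeTable", "CascadeReport", function(object) object@table)
setMethod("filterCounts", "CascadeReport", function(object) object@counts)
setMethod("cascadeSurvivors", "CascadeReport", function(object) {
    tab <- object@table
    as.character(tab$gene[tab$class != "not_candidate"])
})
setMethod("truthTable", "SynthData", function(object) object@truth)
setMethod("promoterSet", "SynthData", function(object) object@promoters)
setMethod("generatorConfig", "SynthData", function(object) object@config)

#' @describeIn SynthData the expression SummarizedExperiment.
#' @export
exprData <- function(object) object@expression

#' @describeIn SynthData the methylation SummarizedExperiment.
#' @export
methData <- function(object) object@methylation

#' @describeIn SynthData the H3K4me3 SummarizedExperiment.
#' @export
h3k4Data <- function(object) object@h3k4

#' @describeIn SynthData the qPCR Ct table.
#' @export
qpcrData <- function(object) object@qpcr
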