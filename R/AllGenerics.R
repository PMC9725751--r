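#' @include AllClasses.R
NULL

#' @export
setGeneric("divisionCounts", function(x) standardGeneric("divisionCounts"))

#' @export
setGeneric("traitValues", function(x, trait) standardGeneric("traitValues"))

#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))

#' @export
setGeneric("nLineages", function(x) standardGeneric("nLineages"))

#' @export
setGeneric("initialCount", function(x) standardGeneric("initialCount"))

#' @export
setGeneric("finalCount", function(x) standardGeneric("finalCount"))

#' @export
setGeneric("obsDuration", function(x) standardGeneric("obsDuration"))

#' @export
setGeneric("ensembleMode", function(x) standardGeneric("ensembleMode"))

#' @export
setGeneric("lineageWeights", function(x) standardGeneric("lineageWeights"))

#' @export
setGeneric("tauLambda", function(x) standardGeneric("tauLambda"))

#' @export
setGeneric("growthRate", function(x) standardGeneric("growthRate"))

#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @export
setGeneric("chronologicalQ", function(x) standardGeneric("chronologicalQ"))

#' @export
setGeneric("retrospectiveQ", function(x) standardGeneric("retrospectiveQ"))

#' @export
setGeneric("fitnessLandscape", function(x) standardGeneric("fitnessLandscape"))

#' @export
setGeneric("cumulantValues", function(x) standardGeneric("cumulantValues"))

#' @export
setGeneric("cumulativeContributions", function(x) standardGeneric("cumulativeContributions"))
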