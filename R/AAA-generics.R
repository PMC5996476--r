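#' @import methods
NULL

#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @export
setGeneric("sampleInfo", function(x, ...) standardGeneric("sampleInfo"))

#' @export
setGeneric("siteRanges", function(x, ...) standardGeneric("siteRanges"))

#' @export
setGeneric("groupOf", function(x, ...) standardGeneric("groupOf"))

#' @export
setGeneric("samplesInGroup", function(x, group, ...)
  standardGeneric("samplesInGroup"))

#' @export
setGeneric("plantedSweeps", function(x) standardGeneric("plantedSweeps"))

#' @export
setGeneric("plantedIbd", function(x) standardGeneric("plantedIbd"))

#' @export
setGeneric("admixtureBlocks", function(x) standardGeneric("admixtureBlocks"))

#' @export
setGeneric("balancedIntervals", function(x) standardGeneric("balancedIntervals"))
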