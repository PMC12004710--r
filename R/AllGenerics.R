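# Generics for the S4 containers.

#' @rdname NmibcCohort-class
#' @param x,object an `NmibcCohort` or `SubtypeModel`.
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))

#' @rdname NmibcCohort-class
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname NmibcCohort-class
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' @rdname NmibcCohort-class
#' @export
setGeneric("clinical", function(x) standardGeneric("clinical"))

#' @rdname NmibcCohort-class
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname NmibcCohort-class
#' @export
setGeneric("exprCounts", function(x) standardGeneric("exprCounts"))

#' @rdname NmibcCohort-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SubtypeModel-class
#' @export
setGeneric("subtypeLabels", function(x) standardGeneric("subtypeLabels"))

#' @rdname SubtypeModel-class
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))

#' @rdname SubtypeModel-class
#' @export
setGeneric("copheneticCoefficients",
           function(x) standardGeneric("copheneticCoefficients"))

#' @rdname SubtypeModel-class
#' @export
setGeneric("subtypeEnrichment",
           function(x) standardGeneric("subtypeEnrichment"))
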