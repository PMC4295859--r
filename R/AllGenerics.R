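#' @rdname accessors
#' @export
setGeneric("expressionLevel", function(x) standardGeneric("expressionLevel"))

#' @rdname accessors
#' @export
setGeneric("designInfo", function(x) standardGeneric("designInfo"))

#' @rdname accessors
#' @export
setGeneric("trendTable", function(x) standardGeneric("trendTable"))

#' @rdname accessors
#' @export
setGeneric("geneLists", function(x) standardGeneric("geneLists"))

#' @rdname accessors
#' @export
setGeneric("candidateSet", function(x) standardGeneric("candidateSet"))

#' @rdname accessors
#' @export
setGeneric("membershipTable", function(x) standardGeneric("membershipTable"))

#' @rdname accessors
#' @export
setGeneric("pairwiseOverlap", function(x) standardGeneric("pairwiseOverlap"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))

#' @rdname accessors
#' @export
setGeneric("plateWells", function(x) standardGeneric("plateWells"))

#' @rdname accessors
#' @export
setGeneric("panelMeasurements",
           function(x) standardGeneric("panelMeasurements"))

#' @rdname accessors
#' @export
setGeneric("panelPatients", function(x) standardGeneric("panelPatients"))

#' @rdname accessors
#' @export
setGeneric("panelSchedule", function(x) standardGeneric("panelSchedule"))
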