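#' @rdname AmpliconSet-accessors
#' @export
setGeneric("ids", function(x) standardGeneric("ids"))

#' @rdname AmpliconSet-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname AmpliconSet-accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname AmpliconSet-accessors
#' @export
setGeneric("inputRanks", function(x) standardGeneric("inputRanks"))

#' @rdname ClusteringResult-accessors
#' @export
setGeneric("nOtu", function(x) standardGeneric("nOtu"))

#' @rdname ClusteringResult-accessors
#' @export
setGeneric("otuAssignments", function(x) standardGeneric("otuAssignments"))

#' @rdname ClusteringResult-accessors
#' @export
setGeneric("otuWeights", function(x) standardGeneric("otuWeights"))

#' @rdname ClusteringResult-accessors
#' @export
setGeneric("otuMembers", function(x) standardGeneric("otuMembers"))

#' @rdname ClusteringResult-accessors
#' @export
setGeneric("graftingRecords", function(x) standardGeneric("graftingRecords"))

#' @rdname MockCommunity-accessors
#' @export
setGeneric("amplicons", function(x) standardGeneric("amplicons"))

#' @rdname MockCommunity-accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
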