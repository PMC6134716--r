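#' Accessors for AmpliconSet
#'
#' @param x an \linkS4class{AmpliconSet}.
#' @return \code{ids}, \code{sequences}: character vectors;
#'   \code{abundances}, \code{inputRanks}: integer vectors.
#' @name AmpliconSet-accessors
#' @aliases ids sequences abundances inputRanks
NULL

#' @rdname AmpliconSet-accessors
#' @export
setMethod("ids", "AmpliconSet", function(x) x@ids)

#' @rdname AmpliconSet-accessors
#' @export
setMethod("sequences", "AmpliconSet", function(x) x@sequences)

#' @rdname AmpliconSet-accessors
#' @export
setMethod("abundances", "AmpliconSet", function(x) x@abundances)

#' @rdname AmpliconSet-accessors
#' @export
setMethod("inputRanks", "AmpliconSet", function(x) x@inputRanks)

#' @describeIn AmpliconSet number of amplicons
#' @param x an AmpliconSet.
#' @export
setMethod("length", "AmpliconSet", function(x) length(x@ids))

#' @describeIn AmpliconSet subset by index, logical mask or id
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "AmpliconSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("AmpliconSet", ids = x@ids[i], sequences = x@sequences[i],
      abundances = x@abundances[i], inputRanks = x@inputRanks[i])
})

setMethod("show", "AmpliconSet", function(object) {
  n <- length(object)
  cat("AmpliconSet with", n, "amplicons\n")
  if (n > 0L) {
    cat("  total abundance:", sum(object@abundances), "\n")
    cat("  sequence lengths:", min(nchar(object@sequences)), "-",
        max(nchar(object@sequences)), "\n")
    k <- min(n, 3L)
    for (i in seq_len(k))
      cat(sprintf("  %s (x%d) %s\n", object@ids[i], object@abundances[i],
                  substr(object@sequences[i], 1L, 40L)))
    if (n > k) cat("  ...\n")
  }
  invisible(NULL)
})

setMethod("show", "SwarmConfig", function(object) {
  cat("SwarmConfig: t =", object@t, "| mode =", object@mode,
      "| breaking =", object@breaking, "| k =", object@k, "\n")
  if (object@mode == "score")
    cat("  delta (match/mismatch/gap open/gap extend):",
        paste(object@delta, collapse = "/"), "\n")
  if (object@fastidious)
    cat("  fastidious: tf =", object@tf, "| boundary b =", object@boundary, "\n")
  invisible(NULL)
})

setMethod("show", "ClusteringResult", function(object) {
  cat("ClusteringResult:", nOtu(object), "OTUs over",
      length(object@amplicons), "amplicons\n")
  if (nrow(object@grafts) > 0L)
    cat("  fastidious grafting:", object@nOtuPreGraft, "OTUs before,",
        nrow(object@grafts), "light OTUs grafted\n")
  invisible(NULL)
})

setMethod("show", "MockCommunity", function(object) {
  cat("MockCommunity:", length(object@centroids), "species,",
      length(object@amplicons), "unique amplicons, total abundance",
      sum(object@amplicons@abundances), "\n")
  invisible(NULL)
})

#' Accessors for ClusteringResult
#'
#' \code{nOtu} gives the final OTU count; \code{otuAssignments} the OTU
#' number per amplicon id; \code{otuWeights} the total abundance per OTU;
#' \code{otuMembers} the membership table; \code{graftingRecords} the
#' applied grafting links.
#'
#' @param x a \linkS4class{ClusteringResult}.
#' @name ClusteringResult-accessors
#' @aliases nOtu otuAssignments otuWeights otuMembers graftingRecords
NULL

#' @rdname ClusteringResult-accessors
#' @export
setMethod("nOtu", "ClusteringResult",
          function(x) length(unique(x@members$otu)))

#' @rdname ClusteringResult-accessors
#' @export
setMethod("otuAssignments", "ClusteringResult",
          function(x) setNames(x@members$otu, x@members$id))

#' @rdname ClusteringResult-accessors
#' @export
setMethod("otuWeights", "ClusteringResult", function(x) {
  ab <- setNames(x@amplicons@abundances, x@amplicons@ids)
  w <- tapply(ab[x@members$id], x@members$otu, sum)
  setNames(as.integer(w), names(w))
})

#' @rdname ClusteringResult-accessors
#' @export
setMethod("otuMembers", "ClusteringResult", function(x) x@members)

#' @rdname ClusteringResult-accessors
#' @export
setMethod("graftingRecords", "ClusteringResult", function(x) x@grafts)

#' Accessors for MockCommunity
#'
#' @param x a \linkS4class{MockCommunity}.
#' @name MockCommunity-accessors
#' @aliases amplicons truthLabels
NULL

#' @rdname MockCommunity-accessors
#' @export
setMethod("amplicons", "MockCommunity", function(x) x@amplicons)

#' @rdname MockCommunity-accessors
#' @export
setMethod("truthLabels", "MockCommunity", function(x) x@truth)
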