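#' AmpliconSet: dereplicated amplicons with abundances
#'
#' Container for a set of amplicons: identifier, upper-case nucleotide
#' sequence, integer abundance (read count after dereplication) and the
#' 0-based rank of first appearance in the input.
#'
#' @slot ids character, amplicon identifiers (header up to the abundance
#'   annotation).
#' @slot sequences character, nucleotide sequences.
#' @slot abundances integer, per-amplicon abundances (all \eqn{\ge 1}).
#' @slot inputRanks integer, 0-based order of first appearance.
#'
#' @examples
#' a <- AmpliconSet(ids = c("a", "b"), sequences = c("ACGT", "AAGT"),
#'                  abundances = c(5L, 2L))
#' abundances(a)
#' @export
setClass("AmpliconSet",
  representation(ids = "character", sequences = "character",
                 abundances = "integer", inputRanks = "integer"))

setValidity("AmpliconSet", function(object) {
  n <- length(object@ids)
  if (length(object@sequences) != n || length(object@abundances) != n ||
      length(object@inputRanks) != n)
    return("ids, sequences, abundances and inputRanks must have equal length")
  if (n == 0L) return(TRUE)
  if (anyNA(object@abundances) || any(object@abundances < 1L))
    return("abundances must be integers >= 1")
  if (any(!nzchar(object@sequences)))
    return("sequences must be non-empty")
  if (anyNA(object@inputRanks) || any(object@inputRanks < 0L))
    return("inputRanks must be >= 0")
  TRUE
})

#' Construct an AmpliconSet
#'
#' @param ids character vector of identifiers.
#' @param sequences character vector of sequences (upper-cased on input).
#' @param abundances integer vector of abundances; defaults to 1 each.
#' @param inputRanks integer vector of 0-based input ranks; defaults to
#'   \code{seq_along(ids) - 1}.
#' @return An \linkS4class{AmpliconSet}.
#' @export
AmpliconSet <- function(ids = character(), sequences = character(),
                        abundances = rep(1L, length(ids)),
                        inputRanks = seq_along(ids) - 1L) {
  new("AmpliconSet", ids = as.character(ids),
      sequences = toupper(as.character(sequences)),
      abundances = as.integer(abundances), inputRanks = as.integer(inputRanks))
}

#' SwarmConfig: parameters of one clustering run
#'
#' @slot t integer, local clustering threshold (\eqn{\ge 1}).
#' @slot mode "edit" (edit distance) or "score" (differences in an optimal
#'   affine-gap alignment).
#' @slot delta integer(4), affine scoring function as (match reward,
#'   mismatch penalty, gap opening penalty, gap extension penalty).
#' @slot breaking logical, restrict links to non-increasing abundance
#'   outwards from the seed.
#' @slot k integer, extra segments of the pigeonhole filter (\eqn{\ge 1}).
#' @slot fastidious logical, run the grafting refinement.
#' @slot tf integer, fastidious threshold (\eqn{\ge t + 1}).
#' @slot boundary integer, light/heavy OTU weight boundary \eqn{b}.
#' @export
setClass("SwarmConfig",
  representation(t = "integer", mode = "character", delta = "integer",
                 breaking = "logical", k = "integer", fastidious = "logical",
                 tf = "integer", boundary = "integer"))

setValidity("SwarmConfig", function(object) {
  if (object@t < 1L) return("t must be >= 1")
  if (!object@mode %in% c("edit", "score")) return("mode must be 'edit' or 'score'")
  if (length(object@delta) != 4L || anyNA(object@delta) || any(object@delta < 0L))
    return("delta must be four non-negative integers")
  if (object@delta[4L] < 1L) return("gap extension penalty must be >= 1")
  if (object@k < 1L) return("k must be >= 1")
  if (object@fastidious && object@tf < object@t + 1L)
    return("fastidious threshold tf must be >= t + 1")
  if (object@boundary < 1L) return("boundary b must be >= 1")
  TRUE
})

#' ClusteringResult: a partition of amplicons into OTUs
#'
#' Holds the amplicons in processing order, one membership row per amplicon
#' (OTU number, parent, link distance, generation, graft flag) in output
#' order, the applied grafting links, and the configuration used.
#'
#' @slot amplicons \linkS4class{AmpliconSet} in processing-priority order.
#' @slot members data.frame with columns \code{id}, \code{otu},
#'   \code{parent}, \code{distance}, \code{generation}, \code{grafted};
#'   rows grouped by OTU in seed order, members in attachment order.
#' @slot grafts data.frame of applied links: \code{heavy}, \code{light},
#'   \code{distance}.
#' @slot nOtuPreGraft integer, OTU count before grafting.
#' @slot config \linkS4class{SwarmConfig}.
#' @export
setClass("ClusteringResult",
  representation(amplicons = "AmpliconSet", members = "data.frame",
                 grafts = "data.frame", nOtuPreGraft = "integer",
                 config = "SwarmConfig"))

setValidity("ClusteringResult", function(object) {
  need <- c("id", "otu", "parent", "distance", "generation", "grafted")
  if (!all(need %in% names(object@members)))
    return(paste("members must have columns", paste(need, collapse = ", ")))
  if (nrow(object@members) != length(object@amplicons@ids))
    return("one membership row per amplicon required")
  TRUE
})

#' MockCommunity: synthetic amplicons with ground-truth species labels
#'
#' @slot amplicons \linkS4class{AmpliconSet} of unique reads.
#' @slot truth character, species label per amplicon (named by amplicon id).
#' @slot centroids character, species centroid sequences (named by label).
#' @slot seed integer, RNG seed the community was generated from.
#' @export
setClass("MockCommunity",
  representation(amplicons = "AmpliconSet", truth = "character",
                 centroids = "character", seed = "integer"))

setValidity("MockCommunity", function(object) {
  if (length(object@truth) != length(object@amplicons@ids))
    return("one truth label per amplicon required")
  if (!identical(names(object@truth), object@amplicons@ids))
    return("truth must be named by amplicon id, in amplicon order")
  TRUE
})
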