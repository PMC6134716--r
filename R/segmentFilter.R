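#' Even partition of a sequence length into segments
#'
#' Tiles a sequence of length \code{l} with \code{n} contiguous, disjoint
#' segments whose lengths differ by at most one; the longer segments are
#' placed last. Start positions are 0-based.
#'
#' @param l sequence length.
#' @param n segment count (\eqn{1 \le n \le l}).
#' @return Integer matrix with columns \code{start} and \code{length}.
#' @examples
#' segmentPartition(10, 3)
#' @export
segmentPartition <- function(l, n) cpp_partition(as.integer(l), as.integer(n))

#' Admissible substring start positions for one segment
#'
#' Multimatch-aware substring selection: the start positions \code{w} in a
#' query of length \code{slen} at which a substring could match segment
#' \code{i} (1-based, at 0-based start \code{p}, length \code{li}) of an
#' indexed sequence of length \code{l}, given threshold \code{tau}. For
#' \code{k = 1} this is the tight Pass-Join window using segment position
#' and length difference; for \code{k > 1} a conservative \eqn{\pm\tau}
#' window is used (complete by the pigeonhole argument).
#'
#' @param slen query sequence length.
#' @param l indexed sequence length (\eqn{|slen - l| \le tau}).
#' @param i segment index, 1-based.
#' @param p 0-based segment start in the indexed sequence.
#' @param li segment length.
#' @param tau distance threshold.
#' @param k extra-segment count of the filter.
#' @return Integer vector of 0-based start positions (possibly empty).
#' @export
selectSubstrings <- function(slen, l, i, p, li, tau, k = 1L)
  cpp_select_positions(as.integer(slen), as.integer(l), as.integer(i),
                       as.integer(p), as.integer(li), as.integer(tau),
                       as.integer(k))

#' Segment-filter candidates for a query sequence
#'
#' First filter stage: builds the inverted segment indices over \code{pool}
#' (each sequence partitioned into \code{tau + k} segments) and returns the
#' indices of all pool sequences that share at least \code{k} distinct
#' segment indices with admissible substrings of \code{query}. Pool
#' sequences too short to partition are returned whenever their length is
#' compatible (they bypass the filter and are meant to be verified
#' directly). Complete: every pool sequence within distance \code{tau} of
#' the query is returned.
#'
#' @param query query sequence (character scalar).
#' @param pool character vector of pool sequences.
#' @param tau distance threshold.
#' @param k extra-segment count (\eqn{\ge 1}).
#' @param self optional 1-based index of \code{query} within \code{pool} to
#'   exclude from the result (0 = no self-match possible).
#' @return Sorted integer vector of 1-based candidate indices.
#' @export
segmentCandidates <- function(query, pool, tau, k = 1L, self = 0L)
  cpp_candidates(pool, query, as.integer(self), as.integer(tau),
                 as.integer(k))

#' Bidirectional segment check
#'
#' Second, pipelined filter stage with the roles of the two sequences
#' swapped: partitions \code{s} into \code{tau + k} segments and requires at
#' least \code{k} of them to occur in \code{c} within their admissible
#' windows. Never fails a pair with true distance \eqn{\le} \code{tau};
#' pairs whose lengths differ by more than \code{tau} always fail.
#'
#' @param s,c the two sequences (character scalars).
#' @param tau distance threshold.
#' @param k extra-segment count.
#' @return Logical scalar.
#' @export
bidirectionalCheck <- function(s, c, tau, k = 1L)
  cpp_bidirectional(s, c, as.integer(tau), as.integer(k))
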