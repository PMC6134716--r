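#' Order amplicons by processing priority
#'
#' Stable total order used everywhere in the pipeline: abundance descending,
#' ties broken by id (lexicographic, C locale) and then by input rank. This
#' makes seeds, generations and all outputs invariant to input record order.
#'
#' @param x an \linkS4class{AmpliconSet}.
#' @return The reordered \linkS4class{AmpliconSet}.
#' @export
sortAmplicons <- function(x) {
  stopifnot(is(x, "AmpliconSet"))
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  x[order(-x@abundances, x@ids, x@inputRanks)]
}

#' Split amplicons into pools by sequence length
#'
#' Amplicons whose lengths differ by more than \code{t} cannot be within
#' distance \code{t} of each other (the edit distance, and likewise the
#' number of differences in any alignment, is bounded below by the length
#' difference). The sorted distinct lengths are therefore cut into maximal
#' runs with consecutive gaps \eqn{\le t}; each run defines a pool that can
#' be clustered independently.
#'
#' @param x an \linkS4class{AmpliconSet}, already ordered by
#'   \code{\link{sortAmplicons}}.
#' @param t integer clustering threshold (\eqn{\ge 1}).
#' @return A list of \linkS4class{AmpliconSet} pools (possibly empty). Each
#'   pool carries its length range as attribute \code{lengthRange}; pools
#'   are ordered by increasing length.
#' @export
buildPools <- function(x, t) {
  stopifnot(is(x, "AmpliconSet"), t >= 1L)
  if (length(x) == 0L) return(list())
  len <- nchar(x@sequences)
  u <- sort(unique(len))
  grp <- cumsum(c(1L, diff(u) > t))
  poolOf <- grp[match(len, u)]
  lapply(seq_len(max(grp)), function(g) {
    p <- x[which(poolOf == g)]
    attr(p, "lengthRange") <- range(u[grp == g])
    p
  })
}
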