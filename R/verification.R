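#' Bounded, length-aware edit distance
#'
#' Banded dynamic programming over the \eqn{2\tau + 1} diagonals admissible
#' given the length difference, with early termination once no cell of a row
#' can stay within \code{tau}. Exact whenever the true edit distance is
#' \eqn{\le \tau}.
#'
#' @param a,b character vectors of sequences, recycled to a common length;
#'   distances are computed pairwise.
#' @param tau non-negative distance bound.
#' @return Integer vector: the exact edit distance where it is
#'   \eqn{\le \tau}, \code{NA} where it exceeds the bound.
#' @examples
#' boundedEditDistance("ACGT", "ACGTT", 2)   # 1
#' boundedEditDistance("AAAA", "TTTT", 2)    # NA (exceeds)
#' @export
boundedEditDistance <- function(a, b, tau) {
  stopifnot(tau >= 0)
  n <- max(length(a), length(b))
  cpp_bounded_edit_batch(rep_len(as.character(a), n),
                         rep_len(as.character(b), n), as.integer(tau))
}

#' Default affine scoring function
#'
#' Match reward 5, mismatch penalty 4, gap opening penalty 12, gap extension
#' penalty 4 (Swarm's defaults). A gap of length \eqn{g} costs
#' \eqn{open + g \cdot extend}, i.e. the extension is charged for every gap
#' column including the first.
#'
#' @return Named integer vector of length 4.
#' @export
defaultScoring <- function()
  c(match = 5L, mismatch = 4L, gapOpen = 12L, gapExtend = 4L)

#' Bounded difference count under an affine scoring function
#'
#' Computes an optimal global affine-gap alignment (Gotoh's three-state
#' recurrence) restricted to a band of \eqn{2\tau + 1} diagonals -- wide
#' enough that no alignment with \eqn{\le \tau} differences is missed -- and
#' counts its differences (mismatch columns plus gap columns). Among
#' co-optimal alignments the one with the fewest differences is counted, so
#' the result is deterministic and independent of traceback order.
#'
#' @param a,b character vectors of sequences, recycled pairwise.
#' @param tau non-negative bound on the difference count.
#' @param delta integer(4) scoring function (match reward, mismatch penalty,
#'   gap opening penalty, gap extension penalty); see
#'   \code{\link{defaultScoring}}.
#' @return Integer vector: the difference count of the optimal alignment
#'   where \eqn{\le \tau}, \code{NA} otherwise.
#' @examples
#' boundedScoreDistance("ACGT", "AGGT", 1)          # 1 (one mismatch)
#' boundedScoreDistance("AAAAGGGG", "AAAGGGG", 1)   # 1 (one gap column)
#' @export
boundedScoreDistance <- function(a, b, tau, delta = defaultScoring()) {
  stopifnot(tau >= 0, length(delta) == 4L)
  n <- max(length(a), length(b))
  cpp_bounded_score_batch(rep_len(as.character(a), n),
                          rep_len(as.character(b), n), as.integer(tau),
                          as.integer(delta))
}

#' Alignment statistics of one optimal affine-gap alignment
#'
#' Unrestricted (full-band) optimal alignment of a single pair, reporting
#' score, difference columns and total aligned columns. Used to derive the
#' percent identity written to the uclust-like output:
#' \eqn{100 (columns - differences) / columns}.
#'
#' @param a,b the two sequences (character scalars).
#' @param delta integer(4) scoring function.
#' @return Named integer vector: \code{score}, \code{diffs}, \code{columns}.
#' @export
alignmentStats <- function(a, b, delta = defaultScoring())
  cpp_align_stats(as.character(a), as.character(b), as.integer(delta))
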