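# contingency table of predicted clusters x truth labels, aligned by name
contingencyOf <- function(predicted, truth) {
  if (is(predicted, "ClusteringResult")) predicted <- otuAssignments(predicted)
  if (is.null(names(predicted)) || is.null(names(truth)))
    stop("predicted and truth must be named by amplicon id")
  if (!setequal(names(predicted), names(truth)))
    stop("predicted must cover exactly the labelled amplicons")
  truth <- truth[names(predicted)]
  if (anyNA(truth)) stop("amplicon without a truth label")
  table(cluster = as.character(predicted), label = as.character(truth))
}

#' Pair-counting precision and recall of a clustering
#'
#' Over all unordered amplicon pairs: a true positive is a pair that is both
#' co-clustered and co-labelled. Recall = TP / co-labelled pairs (the
#' proportion of same-species pairs grouped together); precision =
#' TP / co-clustered pairs (the extent to which grouped pairs are from the
#' same species). An empty denominator yields 1.0 (nothing asserted, nothing
#' wrong). Unweighted: each unique amplicon counts once.
#'
#' @param predicted named cluster assignment per amplicon id (any atomic
#'   type), or a \linkS4class{ClusteringResult}.
#' @param truth named species label per amplicon id; must cover exactly the
#'   amplicons of \code{predicted}.
#' @param weights optional named per-amplicon multiplicities (e.g.
#'   abundances); when supplied, every read rather than every unique
#'   amplicon counts once.
#' @return Named numeric vector: \code{precision}, \code{recall}.
#' @examples
#' p <- c(x1 = 1, x2 = 1, x3 = 1, x4 = 2, x5 = 2)
#' t <- c(x1 = "A", x2 = "A", x3 = "B", x4 = "B", x5 = "B")
#' pairCountingMetrics(p, t)  # 0.5, 0.5
#' @export
pairCountingMetrics <- function(predicted, truth, weights = NULL) {
  if (is(predicted, "ClusteringResult")) predicted <- otuAssignments(predicted)
  if (!is.null(weights)) {
    w <- as.integer(weights[names(predicted)])
    predicted <- rep(predicted, w)
    names(predicted) <- NULL
    truth <- rep(truth[names(weights)], w)
    names(truth) <- NULL
    ct <- table(cluster = as.character(predicted),
                label = as.character(truth))
  } else {
    ct <- contingencyOf(predicted, truth)
  }
  tp <- sum(choose(ct, 2))
  coClustered <- sum(choose(rowSums(ct), 2))
  coLabelled <- sum(choose(colSums(ct), 2))
  c(precision = if (coClustered == 0) 1 else tp / coClustered,
    recall = if (coLabelled == 0) 1 else tp / coLabelled)
}

#' Adjusted Rand index of a clustering
#'
#' Hubert-Arabie adjusted Rand index from the contingency table of predicted
#' clusters and truth labels: the Rand agreement corrected for chance, 1 for
#' identical partitions, 0 expected under random agreement.
#'
#' @inheritParams pairCountingMetrics
#' @return Numeric scalar \eqn{\le 1}.
#' @examples
#' p <- c(x1 = 1, x2 = 1, x3 = 1, x4 = 2, x5 = 2)
#' t <- c(x1 = "A", x2 = "A", x3 = "B", x4 = "B", x5 = "B")
#' adjustedRand(p, t)  # 1/6
#' @export
adjustedRand <- function(predicted, truth) {
  ct <- contingencyOf(predicted, truth)
  n <- sum(ct)
  sumIj <- sum(choose(ct, 2))
  sumI <- sum(choose(rowSums(ct), 2))
  sumJ <- sum(choose(colSums(ct), 2))
  expected <- sumI * sumJ / choose(n, 2)
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(1)   # degenerate: both partitions trivial
  (sumIj - expected) / (maxIdx - expected)
}
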