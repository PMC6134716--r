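#' Build a clustering configuration
#'
#' @param t local clustering threshold (\eqn{\ge 1}); a link between two
#'   amplicons requires distance \eqn{\le t}.
#' @param mode \code{"edit"} for plain edit distance, \code{"score"} for the
#'   number of differences in an optimal affine-gap alignment.
#' @param delta integer(4) affine scoring function, used in \code{"score"}
#'   mode; see \code{\link{defaultScoring}}.
#' @param breaking logical; when \code{TRUE} (default) only links with
#'   non-increasing abundance outwards from the seed are allowed, which
#'   separates centres of abundance instead of chaining them.
#' @param k extra segments of the pigeonhole filter (\eqn{\ge 1}); sequences
#'   are split into \eqn{\tau + k} segments of which at least \eqn{k} must
#'   match. Larger \code{k} filters harder at the price of more segments.
#' @param fastidious logical; run the grafting refinement after clustering.
#' @param tf fastidious threshold (\eqn{\ge t + 1}); default \eqn{2 t},
#'   matching a virtual linking amplicon at distance \eqn{\le t} from both
#'   sides.
#' @param boundary light/heavy OTU boundary \eqn{b}: OTUs with total
#'   abundance \eqn{< b} are light and may be grafted.
#' @return A \linkS4class{SwarmConfig}.
#' @examples
#' swarmConfig(t = 2, fastidious = TRUE)
#' @export
swarmConfig <- function(t = 1L, mode = c("edit", "score"),
                        delta = defaultScoring(), breaking = TRUE, k = 2L,
                        fastidious = FALSE, tf = 2L * t, boundary = 3L) {
  mode <- match.arg(mode)
  new("SwarmConfig", t = as.integer(t), mode = mode,
      delta = as.integer(delta), breaking = isTRUE(breaking),
      k = as.integer(k), fastidious = isTRUE(fastidious), tf = as.integer(tf),
      boundary = as.integer(boundary))
}

#' Partners of one amplicon
#'
#' All available amplicons within distance \eqn{\le t} of amplicon \code{i},
#' found through the segment filter pipeline (candidate generation,
#' bidirectional check, bounded verification). With breaking enabled, only
#' partners whose abundance does not exceed that of \code{i} qualify. The
#' result follows the global priority order.
#'
#' @param x an \linkS4class{AmpliconSet} in priority order (see
#'   \code{\link{sortAmplicons}}).
#' @param i 1-based index of the query amplicon within \code{x}.
#' @param config a \linkS4class{SwarmConfig}.
#' @param available logical mask of amplicons still unassigned; the query
#'   itself is never returned.
#' @param tau threshold to search at (defaults to \code{config@t}; the
#'   fastidious step searches at \code{config@tf}).
#' @return data.frame with columns \code{index} and \code{distance}.
#' @export
findPartners <- function(x, i, config, available = rep(TRUE, length(x)),
                         tau = config@t) {
  stopifnot(is(x, "AmpliconSet"), i >= 1L, i <= length(x))
  m <- cpp_partners(x@sequences, as.integer(available), as.integer(i),
                    as.integer(tau), config@k,
                    if (config@mode == "edit") 0L else 1L, config@delta)
  hits <- data.frame(index = m[, 1L], distance = m[, 2L])
  if (config@breaking)
    hits <- hits[x@abundances[hits$index] <= x@abundances[i], , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# One pool's iterative OTU growth; returns the membership table in
# attachment order (rows grouped by OTU in seed order) plus the OTU count.
clusterPoolCore <- function(pool, config) {
  if (length(pool) == 0L)
    return(list(members = emptyMembers(), nOtu = 0L))
  res <- cpp_cluster_pool(pool@sequences, pool@abundances, config@t,
                          config@k, config@breaking,
                          if (config@mode == "edit") 0L else 1L, config@delta)
  ord <- res$attachOrder
  pid <- res$parent[ord]
  list(members = data.frame(id = pool@ids[ord], otu = res$otu[ord],
                            parent = pool@ids[pid], distance = res$distance[ord],
                            generation = res$generation[ord], grafted = FALSE,
                            stringsAsFactors = FALSE),
       nOtu = res$nOtu)
}

emptyMembers <- function()
  data.frame(id = character(), otu = integer(), parent = character(),
             distance = integer(), generation = integer(), grafted = logical(),
             stringsAsFactors = FALSE)

#' Cluster one amplicon pool
#'
#' Iterative exploration of the amplicon space: the highest-priority
#' unassigned amplicon seeds a new OTU (generation 0); each generation's
#' subseeds, processed in priority order, attach their partners as the next
#' generation (first claim wins), until a generation stays empty and the OTU
#' is closed. Repeats until the pool is exhausted.
#'
#' @param pool an \linkS4class{AmpliconSet}, ordered by
#'   \code{\link{sortAmplicons}}.
#' @param config a \linkS4class{SwarmConfig}; the fastidious flag is ignored
#'   here (refinement operates across pools, see
#'   \code{\link{clusterAmplicons}}).
#' @return A \linkS4class{ClusteringResult} over the pool.
#' @export
clusterPool <- function(pool, config = swarmConfig()) {
  stopifnot(is(pool, "AmpliconSet"), is(config, "SwarmConfig"))
  core <- clusterPoolCore(pool, config)
  new("ClusteringResult", amplicons = pool, members = core$members,
      grafts = emptyGrafts(), nOtuPreGraft = core$nOtu, config = config)
}

#' Cluster amplicons into OTUs
#'
#' Full clustering stage: orders the amplicons by priority, splits them into
#' length pools that cannot share similar amplicons, grows OTUs in each pool
#' with \code{\link{clusterPool}}'s strategy, and numbers the resulting OTUs
#' by the global priority of their seeds. With \code{config@fastidious},
#' light OTUs are subsequently grafted onto heavy ones at threshold
#' \code{config@tf} (see \code{\link{fastidiousRefine}}).
#'
#' @param x an \linkS4class{AmpliconSet} of dereplicated amplicons
#'   (identifiers must be unique).
#' @param config a \linkS4class{SwarmConfig}.
#' @return A \linkS4class{ClusteringResult}.
#' @examples
#' a <- AmpliconSet(ids = c("a", "b", "c"),
#'                  sequences = c("AAAA", "AAAT", "GGGG"),
#'                  abundances = c(10L, 5L, 8L))
#' r <- clusterAmplicons(a, swarmConfig(t = 1))
#' nOtu(r)
#' @export
clusterAmplicons <- function(x, config = swarmConfig()) {
  stopifnot(is(x, "AmpliconSet"), is(config, "SwarmConfig"))
  if (anyDuplicated(x@ids))
    stop("amplicon ids must be unique; run dereplicate() first")
  x <- sortAmplicons(x)
  pools <- buildPools(x, config@t)
  parts <- lapply(pools, clusterPoolCore, config = config)
  members <- do.call(rbind, c(lapply(parts, `[[`, "members"),
                              list(emptyMembers())))
  # renumber OTUs by the global priority rank of their seeds
  if (nrow(members) > 0L) {
    poolTag <- rep.int(seq_along(parts),
                       vapply(parts, function(p) nrow(p$members), 0L))
    key <- poolTag * (max(members$otu, 1L) + 1L) + members$otu
    seedRow <- !duplicated(key)
    seedRank <- match(members$id[seedRow], x@ids)
    newNum <- integer(sum(seedRow))
    newNum[order(seedRank)] <- seq_along(newNum)
    members$otu <- newNum[match(key, key[seedRow])]
    members <- members[order(members$otu), , drop = FALSE]
    rownames(members) <- NULL
  }
  res <- new("ClusteringResult", amplicons = x, members = members,
             grafts = emptyGrafts(),
             nOtuPreGraft = sum(!duplicated(members$otu)), config = config)
  if (config@fastidious) res <- fastidiousRefine(res, config) else res
}
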