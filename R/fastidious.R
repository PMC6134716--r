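emptyGrafts <- function()
  data.frame(heavy = character(), light = character(), distance = integer(),
             stringsAsFactors = FALSE)

#' Split OTUs into light and heavy sets
#'
#' Light OTUs have total abundance (weight) below the boundary \eqn{b},
#' heavy OTUs at least \eqn{b}. Only light OTUs can be grafted, only onto
#' heavy ones.
#'
#' @param result a \linkS4class{ClusteringResult}.
#' @param b abundance boundary (\eqn{\ge 1}).
#' @return List with integer vectors \code{light} and \code{heavy} of OTU
#'   numbers.
#' @export
splitLightHeavy <- function(result, b) {
  stopifnot(is(result, "ClusteringResult"), b >= 1L)
  w <- otuWeights(result)
  list(light = as.integer(names(w))[w < b],
       heavy = as.integer(names(w))[w >= b])
}

#' Enumerate grafting links
#'
#' Indexes the amplicons of light OTUs at the fastidious threshold
#' \code{tf} and searches grafting partners for the amplicons of heavy OTUs
#' among them. All (heavy, light) pairs within distance \code{tf} are found
#' through the segment filter plus verification; each light amplicon then
#' keeps only the heavy partner of maximum abundance (ties: id).
#'
#' @param lightAmps,heavyAmps \linkS4class{AmpliconSet}s of the amplicons in
#'   light resp. heavy OTUs.
#' @param tf fastidious threshold.
#' @param config a \linkS4class{SwarmConfig} (mode, delta and k are used;
#'   distances are computed in the same mode as the main clustering).
#' @return data.frame with columns \code{heavy}, \code{light} (ids),
#'   \code{distance}, \code{heavyAbundance}, \code{lightAbundance}.
#' @export
enumerateGraftingLinks <- function(lightAmps, heavyAmps, tf, config) {
  stopifnot(is(lightAmps, "AmpliconSet"), is(heavyAmps, "AmpliconSet"))
  m <- cpp_graft_links(lightAmps@sequences, heavyAmps@sequences,
                       as.integer(tf), config@k,
                       if (config@mode == "edit") 0L else 1L, config@delta)
  if (nrow(m) == 0L) {
    return(data.frame(heavy = character(), light = character(),
                      distance = integer(), heavyAbundance = integer(),
                      lightAbundance = integer(), stringsAsFactors = FALSE))
  }
  links <- data.frame(heavy = heavyAmps@ids[m[, 1L]],
                      light = lightAmps@ids[m[, 2L]],
                      distance = m[, 3L],
                      heavyAbundance = heavyAmps@abundances[m[, 1L]],
                      lightAbundance = lightAmps@abundances[m[, 2L]],
                      stringsAsFactors = FALSE)
  # one link per light amplicon: heavy partner of maximum abundance, ties by id
  ord <- cOrder(links$light, -links$heavyAbundance, links$heavy)
  links <- links[ord, , drop = FALSE]
  links <- links[!duplicated(links$light), , drop = FALSE]
  rownames(links) <- NULL
  links
}

#' Order grafting links
#'
#' Heavy abundance descending, then light abundance descending; residual
#' ties broken by heavy id then light id (lexicographic, C locale) to make
#' the strict partial order of the grafting step total.
#'
#' @param links data.frame as returned by
#'   \code{\link{enumerateGraftingLinks}}.
#' @return The reordered data.frame.
#' @export
sortGraftingLinks <- function(links) {
  ord <- cOrder(-links$heavyAbundance, -links$lightAbundance, links$heavy,
                links$light)
  out <- links[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# order() under the C collation so that id tie-breaks are locale-independent
cOrder <- function(...) {
  old <- Sys.getlocale("LC_COLLATE")
  on.exit(Sys.setlocale("LC_COLLATE", old), add = TRUE)
  Sys.setlocale("LC_COLLATE", "C")
  order(...)
}

#' Apply grafting links to a clustering
#'
#' Scans the sorted links; a link (h, l) is valid if l's OTU has not been
#' grafted yet. On a valid link all amplicons of l's light OTU move into h's
#' OTU: l is re-linked to h (distance = link distance, generation =
#' generation of h + 1) and the light OTU's member graph is re-rooted at l,
#' preserving its edges. The virtual linking amplicon itself is never
#' materialised. Grafted OTUs disappear from the top level; remaining OTUs
#' are renumbered in seed order.
#'
#' @param links sorted links (see \code{\link{sortGraftingLinks}}).
#' @param result the pre-refinement \linkS4class{ClusteringResult}.
#' @return A \linkS4class{ClusteringResult} with updated membership and the
#'   applied links in \code{graftingRecords}.
#' @export
applyGrafts <- function(links, result) {
  members <- result@members
  otuOf <- setNames(members$otu, members$id)
  genOf <- setNames(members$generation, members$id)
  target <- setNames(members$otu, members$id)  # final OTU per amplicon
  grafted <- logical(max(members$otu, 0L))     # light OTU already grafted?
  applied <- emptyGrafts()
  pieces <- list()                             # re-rooted light blocks per OTU
  for (z in seq_len(nrow(links))) {
    h <- links$heavy[z]; l <- links$light[z]
    lo <- otuOf[[l]]
    if (grafted[lo]) next
    ho <- target[[h]]                          # follow h's current OTU
    grafted[lo] <- TRUE
    block <- rerootLightOtu(members[members$otu == lo, , drop = FALSE], l, h,
                            links$distance[z], genOf[[h]],
                            result@amplicons@ids)
    target[block$id] <- ho
    genOf[block$id] <- block$generation
    pieces[[length(pieces) + 1L]] <- cbind(block, toOtu = ho)
    applied <- rbind(applied,
                     data.frame(heavy = h, light = l,
                                distance = links$distance[z],
                                stringsAsFactors = FALSE))
  }
  keepOtu <- sort(unique(members$otu[!grafted[members$otu]]))
  renum <- setNames(seq_along(keepOtu), keepOtu)
  out <- list()
  graftBlocks <- if (length(pieces) > 0L) do.call(rbind, pieces) else NULL
  for (o in keepOtu) {
    blk <- members[members$otu == o, , drop = FALSE]
    blk$otu <- renum[[as.character(o)]]
    out[[length(out) + 1L]] <- blk
    if (!is.null(graftBlocks)) {
      gb <- graftBlocks[graftBlocks$toOtu == o, , drop = FALSE]
      if (nrow(gb) > 0L) {
        gb$otu <- renum[[as.character(o)]]
        out[[length(out) + 1L]] <- gb[names(members)]
      }
    }
  }
  members2 <- do.call(rbind, c(out, list(emptyMembers())))
  rownames(members2) <- NULL
  new("ClusteringResult", amplicons = result@amplicons, members = members2,
      grafts = applied, nOtuPreGraft = result@nOtuPreGraft,
      config = result@config)
}

# Re-root the member graph of one light OTU at amplicon l, which becomes a
# child of heavy amplicon h. Edge weights are preserved; generations count
# from h. BFS neighbours are visited in global priority order.
rerootLightOtu <- function(block, l, h, linkDist, genH, priorityIds) {
  edgeChild <- block$id[!is.na(block$parent)]
  edgeParent <- block$parent[!is.na(block$parent)]
  edgeDist <- block$distance[!is.na(block$parent)]
  adj <- list()
  for (i in seq_along(edgeChild)) {
    adj[[edgeChild[i]]] <- rbind(adj[[edgeChild[i]]],
                                 data.frame(to = edgeParent[i], d = edgeDist[i],
                                            stringsAsFactors = FALSE))
    adj[[edgeParent[i]]] <- rbind(adj[[edgeParent[i]]],
                                  data.frame(to = edgeChild[i], d = edgeDist[i],
                                             stringsAsFactors = FALSE))
  }
  n <- nrow(block)
  res <- data.frame(id = character(n), otu = 0L, parent = character(n),
                    distance = integer(n), generation = integer(n),
                    grafted = logical(n), stringsAsFactors = FALSE)
  seen <- setNames(logical(n), block$id)
  res[1L, ] <- list(l, 0L, h, as.integer(linkDist), genH + 1L, TRUE)
  seen[[l]] <- TRUE
  filled <- 1L
  q <- l
  gen <- setNames(integer(n), block$id)
  gen[[l]] <- genH + 1L
  while (length(q) > 0L) {
    u <- q[[1L]]; q <- q[-1L]
    nb <- adj[[u]]
    if (is.null(nb)) next
    nb <- nb[!seen[nb$to], , drop = FALSE]
    if (nrow(nb) == 0L) next
    nb <- nb[order(match(nb$to, priorityIds)), , drop = FALSE]
    for (i in seq_len(nrow(nb))) {
      v <- nb$to[i]
      seen[[v]] <- TRUE
      gen[[v]] <- gen[[u]] + 1L
      filled <- filled + 1L
      res[filled, ] <- list(v, 0L, u, as.integer(nb$d[i]), gen[[v]], FALSE)
      q <- c(q, v)
    }
  }
  res
}

#' Fastidious refinement of a clustering
#'
#' Generalised fastidious step: splits the OTUs at boundary
#' \code{config@boundary}, enumerates grafting links at threshold
#' \code{config@tf} (heavy amplicons queried against an index of the light
#' ones), reduces and orders them, and applies them with the
#' one-graft-per-light-OTU rule. A no-op when there are no light or no heavy
#' OTUs.
#'
#' @param result a \linkS4class{ClusteringResult} from the non-fastidious
#'   stage.
#' @param config a \linkS4class{SwarmConfig} with \code{fastidious = TRUE}.
#' @return The refined \linkS4class{ClusteringResult}.
#' @export
fastidiousRefine <- function(result, config = result@config) {
  stopifnot(is(result, "ClusteringResult"))
  lh <- splitLightHeavy(result, config@boundary)
  if (length(lh$light) == 0L || length(lh$heavy) == 0L) return(result)
  lightIds <- result@members$id[result@members$otu %in% lh$light]
  heavyIds <- result@members$id[result@members$otu %in% lh$heavy]
  links <- enumerateGraftingLinks(result@amplicons[lightIds],
                                  result@amplicons[heavyIds],
                                  config@tf, config)
  if (nrow(links) == 0L) return(result)
  applyGrafts(sortGraftingLinks(links), result)
}
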