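#' Output formatters for a clustering result
#'
#' The five Swarm-compatible output types. All formatters return character
#' vectors (one element per line) so they can be inspected without touching
#' the file system; \code{\link{writeOtuFiles}} writes them.
#'
#' \describe{
#'   \item{membership}{one line per OTU: member labels (abundance annotation
#'     re-attached) separated by single spaces, seed first, members in
#'     attachment order, OTUs in seed order.}
#'   \item{statistics}{one tab-separated line per OTU: number of unique
#'     amplicons, total abundance, seed id, seed abundance, number of
#'     members with abundance 1, maximum generation, maximum number of
#'     steps (summed link distances) from the seed.}
#'   \item{seeds}{FASTA with one record per OTU: the seed id annotated with
#'     the OTU's total abundance, and the seed sequence.}
#'   \item{uclust}{uclust-like table with S/H/C records; H records carry the
#'     percent identity of member and seed, computed as
#'     \eqn{100 (columns - differences) / columns} from an optimal
#'     alignment.}
#'   \item{internal}{one tab-separated line per link: parent id, child id,
#'     distance, OTU number (1-based), child generation; links applied by
#'     the fastidious step carry a trailing flag field \code{G}.}
#' }
#'
#' @param result a \linkS4class{ClusteringResult}.
#' @param dialect,separator abundance annotation dialect for labels, as in
#'   \code{\link{readAmplicons}}.
#' @return Character vector of output lines.
#' @name otu-output
NULL

# split by OTU number in numeric order (factor levels would sort "10" < "2")
splitByOtu <- function(x, otu) split(x, factor(otu, levels = sort(unique(otu))))

resultLabels <- function(result, dialect, separator) {
  ab <- setNames(result@amplicons@abundances, result@amplicons@ids)
  function(id) ampliconLabel(id, ab[[id]], dialect, separator)
}

#' @rdname otu-output
#' @export
otuMembershipLines <- function(result, dialect = "separator",
                               separator = "_") {
  lab <- resultLabels(result, dialect, separator)
  m <- result@members
  vapply(splitByOtu(m$id, m$otu),
         function(idv) paste(vapply(idv, lab, ""), collapse = " "), "")
}

# summed link distances from the seed, per member, rows in member order
memberRadii <- function(m) {
  radius <- setNames(integer(nrow(m)), m$id)
  for (i in seq_len(nrow(m)))
    if (!is.na(m$parent[i]) && m$parent[i] %in% names(radius))
      radius[[m$id[i]]] <- radius[[m$parent[i]]] + m$distance[i]
  radius
}

#' @rdname otu-output
#' @export
otuStatistics <- function(result) {
  ab <- setNames(result@amplicons@abundances, result@amplicons@ids)
  blocks <- splitByOtu(result@members, result@members$otu)
  rows <- lapply(blocks, function(m) {
    radius <- memberRadii(m)
    data.frame(uniqueAmplicons = nrow(m),
               weight = sum(ab[m$id]),
               seed = m$id[1L],
               seedAbundance = ab[[m$id[1L]]],
               singletons = sum(ab[m$id] == 1L),
               maxGeneration = max(m$generation),
               maxRadius = max(radius),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname otu-output
#' @export
otuStatisticsLines <- function(result) {
  s <- otuStatistics(result)
  paste(s$uniqueAmplicons, s$weight, s$seed, s$seedAbundance, s$singletons,
        s$maxGeneration, s$maxRadius, sep = "\t")
}

#' @rdname otu-output
#' @export
otuSeedLines <- function(result, dialect = "separator", separator = "_") {
  m <- result@members
  seqOf <- setNames(result@amplicons@sequences, result@amplicons@ids)
  w <- otuWeights(result)
  seeds <- vapply(splitByOtu(m$id, m$otu), `[`, "", 1L)
  lines <- character(0)
  for (o in seq_along(seeds)) {
    lines <- c(lines,
               paste0(">", ampliconLabel(seeds[[o]], w[[as.character(o)]],
                                         dialect, separator)),
               seqOf[[seeds[[o]]]])
  }
  lines
}

#' @rdname otu-output
#' @export
otuUclustLines <- function(result, dialect = "separator", separator = "_") {
  lab <- resultLabels(result, dialect, separator)
  seqOf <- setNames(result@amplicons@sequences, result@amplicons@ids)
  delta <- if (result@config@mode == "score") result@config@delta
           else c(0L, 1L, 0L, 1L)  # unit costs: an optimal edit alignment
  m <- result@members
  lines <- character(0)
  for (blk in splitByOtu(m, m$otu)) {
    clu <- blk$otu[1L] - 1L
    seed <- blk$id[1L]
    lines <- c(lines, paste("S", clu, nchar(seqOf[[seed]]), "*", "*", "*",
                            "*", "*", lab(seed), "*", sep = "\t"))
    for (i in seq_len(nrow(blk))[-1L]) {
      st <- alignmentStats(seqOf[[seed]], seqOf[[blk$id[i]]], delta)
      pct <- 100 * (st[["columns"]] - st[["diffs"]]) / st[["columns"]]
      lines <- c(lines, paste("H", clu, nchar(seqOf[[blk$id[i]]]),
                              sprintf("%.1f", pct), "+", "0", "0", "*",
                              lab(blk$id[i]), lab(seed), sep = "\t"))
    }
    lines <- c(lines, paste("C", clu, nrow(blk), "*", "*", "*", "*", "*",
                            lab(seed), "*", sep = "\t"))
  }
  lines
}

#' @rdname otu-output
#' @export
otuInternalLines <- function(result) {
  m <- result@members
  m <- m[!is.na(m$parent), , drop = FALSE]
  if (nrow(m) == 0L) return(character(0))
  base <- paste(m$parent, m$id, m$distance, m$otu, m$generation, sep = "\t")
  ifelse(m$grafted, paste(base, "G", sep = "\t"), base)
}

#' Write the requested output files
#'
#' Writes any subset of the five output types (see \link{otu-output});
#' requesting none is an error. All files are newline-terminated UTF-8.
#'
#' @param result a finalised \linkS4class{ClusteringResult}.
#' @param membership,statistics,seeds,uclust,internal file paths, or
#'   \code{NULL} to skip an output type.
#' @param dialect,separator abundance annotation dialect for labels.
#' @return Invisibly, the character vector of paths written.
#' @export
writeOtuFiles <- function(result, membership = NULL, statistics = NULL,
                          seeds = NULL, uclust = NULL, internal = NULL,
                          dialect = "separator", separator = "_") {
  paths <- c(membership, statistics, seeds, uclust, internal)
  if (length(paths) == 0L)
    stop("no output requested: provide at least one of membership, ",
         "statistics, seeds, uclust, internal")
  if (!is.null(membership))
    writeLines(otuMembershipLines(result, dialect, separator), membership)
  if (!is.null(statistics))
    writeLines(otuStatisticsLines(result), statistics)
  if (!is.null(seeds))
    writeLines(otuSeedLines(result, dialect, separator), seeds)
  if (!is.null(uclust))
    writeLines(otuUclustLines(result, dialect, separator), uclust)
  if (!is.null(internal))
    writeLines(otuInternalLines(result), internal)
  invisible(paths)
}
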