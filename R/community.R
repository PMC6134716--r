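#' Generate a synthetic mock community with ground truth
#'
#' Emulates a dereplicated amplicon data set of known composition: species
#' centroid sequences drawn uniformly over \{A,C,G,T\} with a minimum
#' pairwise edit distance (\code{separation}), species total read counts
#' skewed like a log-normal distribution (a few abundant and many rare
#' species), and reads derived from their centroid by independent per-base
#' point mutations, a fraction of which are indels. Identical reads are
#' dereplicated with summed abundance; the originating species label is kept
#' per unique amplicon. Fully reproducible from \code{seed}.
#'
#' What it does not emulate: chimeras, homopolymer-specific error profiles,
#' length variation of real 16S variable regions beyond mutation indels, and
#' cross-species sequence overlap (near-identical reads arising from two
#' species are resolved to the more abundant origin and are vanishingly rare
#' at the default separation).
#'
#' @param nSpecies number of species (\eqn{\ge 1}).
#' @param readsMeanlog,readsSdlog log-normal parameters of the species total
#'   read counts (counts are rounded up to at least 1).
#' @param mutationRate per-base probability that a read position is mutated.
#' @param indelFraction proportion of mutations that are indels (half
#'   insertions, half deletions) rather than substitutions.
#' @param length centroid sequence length in bp.
#' @param separation minimum pairwise edit distance between centroids.
#' @param seed RNG seed (integer).
#' @return A \linkS4class{MockCommunity}.
#' @examples
#' cm <- generateCommunity(nSpecies = 3, readsMeanlog = log(20), seed = 1)
#' amplicons(cm)
#' @export
generateCommunity <- function(nSpecies = 20L, readsMeanlog = log(200),
                              readsSdlog = 1, mutationRate = 0.002,
                              indelFraction = 0.1, length = 250L,
                              separation = 10L, seed = 1L) {
  stopifnot(nSpecies >= 1L, mutationRate >= 0, mutationRate <= 1,
            indelFraction >= 0, indelFraction <= 1, length >= 1L)
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  labels <- sprintf("sp%02d", seq_len(nSpecies))

  centroids <- character(0)
  tries <- 0L
  while (length(centroids) < nSpecies) {
    cand <- paste(sample(bases, length, replace = TRUE), collapse = "")
    ok <- TRUE
    if (separation > 0L && length(centroids) > 0L)
      ok <- all(is.na(boundedEditDistance(cand, centroids, separation - 1L)))
    if (ok) centroids <- c(centroids, cand)
    tries <- tries + 1L
    if (tries > 100L * nSpecies)
      stop("could not place ", nSpecies, " centroids at separation ",
           separation, " within the retry budget")
  }
  names(centroids) <- labels

  totals <- pmax(1L, as.integer(round(rlnorm(nSpecies, readsMeanlog,
                                             readsSdlog))))
  seqs <- character(0); abund <- integer(0); spec <- character(0)
  for (s in seq_len(nSpecies)) {
    reads <- replicate(totals[s], mutateRead(centroids[[s]], mutationRate,
                                             indelFraction, bases))
    tab <- table(reads)
    seqs <- c(seqs, names(tab))
    abund <- c(abund, as.integer(tab))
    spec <- c(spec, rep(labels[s], length(tab)))
  }
  # resolve (rare) identical sequences arising from different species: the
  # occurrence with the larger abundance keeps the read, earlier species wins
  # ties, so every unique amplicon has exactly one ground-truth label
  ord <- order(seqs, -abund, spec)
  dup <- duplicated(seqs[ord])
  keep <- sort(seq_along(seqs)[ord][!dup])
  seqs <- seqs[keep]; abund <- abund[keep]; spec <- spec[keep]

  ids <- sprintf("r%05d", seq_along(seqs))
  amps <- AmpliconSet(ids = ids, sequences = seqs, abundances = abund)
  new("MockCommunity", amplicons = amps, truth = setNames(spec, ids),
      centroids = centroids, seed = as.integer(seed))
}

# apply point mutations to one read: substitutions plus indels
mutateRead <- function(seqStr, rate, indelFraction, bases) {
  if (rate <= 0) return(seqStr)
  chars <- strsplit(seqStr, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  nmut <- rbinom(1L, n, rate)
  if (nmut == 0L) return(seqStr)
  pos <- sort(sample.int(n, nmut))
  isIndel <- runif(nmut) < indelFraction
  out <- chars
  drop <- logical(n)
  ins <- vector("list", n)
  for (z in seq_len(nmut)) {
    p <- pos[z]
    if (!isIndel[z]) {
      out[p] <- sample(setdiff(bases, chars[p]), 1L)
    } else if (runif(1L) < 0.5) {
      drop[p] <- TRUE
    } else {
      ins[[p]] <- sample(bases, 1L)
    }
  }
  pieces <- character(0)
  for (p in seq_len(n)) {
    if (!is.null(ins[[p]])) pieces <- c(pieces, ins[[p]])
    if (!drop[p]) pieces <- c(pieces, out[p])
  }
  if (length(pieces) == 0L) return(seqStr)
  paste(pieces, collapse = "")
}

#' Write a mock community to disk
#'
#' FASTA with abundance annotations plus a two-column tab-separated ground
#' truth file (amplicon id, species label).
#'
#' @param community a \linkS4class{MockCommunity}.
#' @param fasta,truth output paths.
#' @param dialect,separator abundance annotation dialect.
#' @return Invisibly, the two paths.
#' @export
writeCommunity <- function(community, fasta, truth, dialect = "separator",
                           separator = "_") {
  a <- community@amplicons
  lines <- as.vector(rbind(
    paste0(">", ampliconLabel(a@ids, a@abundances, dialect, separator)),
    a@sequences))
  writeLines(lines, fasta)
  writeLines(paste(names(community@truth), community@truth, sep = "\t"),
             truth)
  invisible(c(fasta, truth))
}
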