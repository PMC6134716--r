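#' Read abundance-annotated FASTA files
#'
#' Parses one or more FASTA files of dereplicated amplicons whose headers
#' carry abundance annotations, either as a trailing
#' \code{<separator><integer>} (Swarm convention, e.g. \code{>s1_13}) or as a
#' \code{;size=N} field (USEARCH convention, e.g. \code{>s1;size=13;}).
#' Multiple files are concatenated in order before ranks are assigned.
#'
#' @param files character vector of FASTA paths (plain or gzip).
#' @param dialect abundance annotation dialect: \code{"separator"} or
#'   \code{"usearch"}.
#' @param separator single character separating id and abundance in the
#'   \code{"separator"} dialect.
#' @param strict logical; if \code{TRUE} (default) a missing or invalid
#'   abundance annotation aborts with a message naming the record, if
#'   \code{FALSE} a missing annotation defaults the abundance to 1.
#' @return An \linkS4class{AmpliconSet} in file order, sequences upper-cased,
#'   with 0-based \code{inputRanks}.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1_13", "ACGT", ">s2_5", "AC", "GT"), f)
#' readAmplicons(f)
#' @export
readAmplicons <- function(files, dialect = c("separator", "usearch"),
                          separator = "_", strict = TRUE) {
  dialect <- match.arg(dialect)
  stopifnot(length(files) >= 1L, all(file.exists(files)))
  recs <- do.call(c, lapply(files, Biostrings::readBStringSet))
  headers <- names(recs)
  seqs <- toupper(as.character(recs))
  if (any(!nzchar(seqs)))
    stop("FASTA record with empty sequence: ",
         headers[which(!nzchar(seqs))[1L]])
  ann <- parseAbundanceAnnotation(headers, dialect, separator)
  miss <- is.na(ann$abundance) & !ann$present
  bad <- ann$present & is.na(ann$abundance)
  if (any(bad))
    stop("invalid abundance annotation in record '", headers[which(bad)[1L]], "'")
  if (strict && any(miss))
    stop("missing abundance annotation in record '", headers[which(miss)[1L]],
         "' (use strict = FALSE to default to 1)")
  ab <- ann$abundance
  ab[miss] <- 1L
  AmpliconSet(ids = ann$id, sequences = seqs, abundances = ab,
              inputRanks = seq_along(headers) - 1L)
}

# Split headers into id and abundance under one dialect. Returns a list with
# id, abundance (NA when absent or invalid) and present (annotation found).
parseAbundanceAnnotation <- function(headers, dialect, separator = "_") {
  headers <- sub("\\s.*$", "", headers)  # drop description after first blank
  if (dialect == "separator") {
    pat <- paste0("^(.*)", escapeRegex(separator), "([0-9]+)$")
  } else {
    pat <- "^(.*?);size=([0-9]+);?$"
  }
  hit <- grepl(pat, headers)
  id <- ifelse(hit, sub(pat, "\\1", headers), headers)
  ab <- rep(NA_integer_, length(headers))
  ab[hit] <- as.integer(sub(pat, "\\2", headers[hit]))
  ab[!is.na(ab) & ab < 1L] <- NA_integer_
  list(id = id, abundance = ab, present = hit)
}

escapeRegex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# Re-attach the abundance annotation to an id under one dialect.
ampliconLabel <- function(id, abundance, dialect = "separator",
                          separator = "_") {
  if (dialect == "usearch") paste0(id, ";size=", abundance, ";")
  else paste0(id, separator, abundance)
}

#' Filter amplicons by length and alphabet
#'
#' Keeps exactly the amplicons whose sequence length lies in
#' \code{[minLength, maxLength]} and whose characters all belong to
#' \code{alphabet}; relative order is preserved. Reads with ambiguous bases
#' (e.g. \code{N}) are removed by the default alphabet.
#'
#' @param x an \linkS4class{AmpliconSet}.
#' @param minLength,maxLength inclusive length bounds.
#' @param alphabet character vector of allowed residues.
#' @return The filtered \linkS4class{AmpliconSet} (possibly empty).
#' @export
filterAmplicons <- function(x, minLength = 1L, maxLength = Inf,
                            alphabet = c("A", "C", "G", "T")) {
  stopifnot(is(x, "AmpliconSet"), minLength <= maxLength,
            length(alphabet) >= 1L)
  len <- nchar(x@sequences)
  ok <- len >= minLength & len <= maxLength
  pat <- paste0("^[", paste(alphabet, collapse = ""), "]*$")
  ok <- ok & grepl(pat, x@sequences)
  x[which(ok)]
}

#' Dereplicate amplicons
#'
#' Merges amplicons with identical sequences, summing abundances. The merged
#' amplicon takes id and input rank from the member with the highest
#' abundance (ties: smallest input rank). Idempotent; conserves total
#' abundance. Output keeps the input-rank order of the representatives.
#'
#' @param x an \linkS4class{AmpliconSet}.
#' @return A dereplicated \linkS4class{AmpliconSet}.
#' @export
dereplicate <- function(x) {
  stopifnot(is(x, "AmpliconSet"))
  if (length(x) == 0L) return(x)
  grp <- match(x@sequences, unique(x@sequences))
  ord <- order(grp, -x@abundances, x@inputRanks)
  rep_i <- ord[!duplicated(grp[ord])]          # representative per group
  ab <- as.integer(tapply(x@abundances, grp, sum))
  keep <- order(x@inputRanks[rep_i])
  AmpliconSet(ids = x@ids[rep_i][keep],
              sequences = x@sequences[rep_i][keep],
              abundances = ab[grp[rep_i]][keep],
              inputRanks = x@inputRanks[rep_i][keep])
}
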