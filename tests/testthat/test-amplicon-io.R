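writeFasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

test_that("FASTA parsing handles both abundance dialects", {
  f <- writeFasta(c(">s1_13", "ACGT", ">s2_5", "ac", "gt"))
  a <- readAmplicons(f)
  expect_equal(ids(a), c("s1", "s2"))
  expect_equal(sequences(a), c("ACGT", "ACGT"))  # multi-line + upper-cased
  expect_equal(abundances(a), c(13L, 5L))
  expect_equal(inputRanks(a), c(0L, 1L))

  g <- writeFasta(c(">s1;size=13;", "ACGT", ">s2;size=2", "GGGG"))
  b <- readAmplicons(g, dialect = "usearch")
  expect_equal(ids(b), c("s1", "s2"))
  expect_equal(abundances(b), c(13L, 2L))
})

test_that("strict mode rejects missing or invalid annotations by record name", {
  f <- writeFasta(c(">s1_3", "ACGT", ">s2", "GGGG"))
  expect_error(readAmplicons(f), "s2")
  a <- readAmplicons(f, strict = FALSE)
  expect_equal(abundances(a), c(3L, 1L))
  z <- writeFasta(c(">s1_0", "ACGT"))
  expect_error(readAmplicons(z), "invalid")
  expect_error(readAmplicons(z, strict = FALSE), "invalid")
})

test_that("length and alphabet filtering applies both rules in order", {
  a <- AmpliconSet(ids = c("a", "b", "c"),
                   sequences = c("ACGT", "ACNGT", "AC"),
                   abundances = c(1L, 1L, 1L))
  f <- filterAmplicons(a, minLength = 3, maxLength = 10)
  expect_equal(sequences(f), "ACGT")
  # no bounds, full IUPAC alphabet: identity
  iupac <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  expect_equal(sequences(filterAmplicons(a, alphabet = iupac)), sequences(a))
  # all shorter than minimum: empty
  expect_length(filterAmplicons(a, minLength = 50), 0L)
})

test_that("dereplication sums abundances and picks the dominant representative", {
  a <- AmpliconSet(ids = c("a", "b"), sequences = c("ACGT", "ACGT"),
                   abundances = c(3L, 5L))
  d <- dereplicate(a)
  expect_equal(ids(d), "b")
  expect_equal(abundances(d), 8L)
  # all distinct: unchanged
  u <- AmpliconSet(ids = c("a", "b"), sequences = c("ACGT", "TTTT"),
                   abundances = c(2L, 7L))
  expect_equal(ids(dereplicate(u)), ids(u))
  # abundance tie: earlier input rank wins
  tie <- AmpliconSet(ids = c("a", "b"), sequences = c("ACGT", "ACGT"),
                     abundances = c(2L, 2L))
  expect_equal(ids(dereplicate(tie)), "a")
  # idempotence and abundance conservation
  expect_equal(dereplicate(d), d)
  expect_equal(sum(abundances(d)), sum(abundances(a)))
})

clusterExample <- function() {
  a <- AmpliconSet(ids = c("a", "b", "c"),
                   sequences = c("AAAA", "AAAT", "AATT"),
                   abundances = c(10L, 5L, 3L))
  clusterAmplicons(a, swarmConfig(t = 1))
}

test_that("membership, statistics and internal outputs match the documented formats", {
  r <- clusterExample()
  expect_equal(unname(otuMembershipLines(r)), "a_10 b_5 c_3")
  expect_equal(otuStatisticsLines(r), "3\t18\ta\t10\t0\t2\t2")
  expect_equal(otuInternalLines(r), c("a\tb\t1\t1\t1", "b\tc\t1\t1\t2"))
})

test_that("statistics totals conserve abundance and amplicon counts", {
  cm <- testCommunity(seed = 11, nSpecies = 5L)
  r <- clusterAmplicons(amplicons(cm), swarmConfig(t = 2))
  s <- otuStatistics(r)
  expect_equal(sum(s$weight), sum(abundances(amplicons(cm))))
  expect_equal(sum(s$uniqueAmplicons), length(amplicons(cm)))
})

test_that("seed FASTA round-trips through the parser", {
  cm <- testCommunity(seed = 12, nSpecies = 4L)
  r <- clusterAmplicons(amplicons(cm), swarmConfig(t = 1))
  f <- tempfile(fileext = ".fasta")
  writeOtuFiles(r, seeds = f)
  back <- readAmplicons(f)
  s <- otuStatistics(r)
  expect_equal(ids(back), s$seed)
  expect_equal(abundances(back), s$weight)
  seqOf <- setNames(sequences(r@amplicons), ids(r@amplicons))
  expect_equal(sequences(back), unname(seqOf[s$seed]))
})

test_that("requesting no output at all is an error", {
  r <- clusterExample()
  expect_error(writeOtuFiles(r), "no output requested")
})

test_that("uclust-like output has S/H/C records with identities", {
  r <- clusterExample()
  lines <- otuUclustLines(r)
  expect_equal(substr(lines, 1, 1), c("S", "H", "H", "C"))
  h <- strsplit(lines[2], "\t")[[1]]
  expect_equal(h[4], "75.0")  # AAAT vs AAAA: 3 of 4 columns identical
  cl <- strsplit(lines[4], "\t")[[1]]
  expect_equal(cl[3], "3")    # member count in the C record
})
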