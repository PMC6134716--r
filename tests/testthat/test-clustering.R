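poolOf <- function(ids, seqs, ab)
  sortAmplicons(AmpliconSet(ids = ids, sequences = seqs, abundances = ab))

test_that("partner search respects threshold and abundance rule", {
  x <- poolOf(c("a", "b", "c"), c("AAAA", "AAAT", "TTTT"), c(10L, 5L, 7L))
  cfg <- swarmConfig(t = 1)
  ia <- which(ids(x) == "a")
  p <- findPartners(x, ia, cfg)
  expect_equal(ids(x)[p$index], "b")     # d(a,b)=1, d(a,c)=4
  expect_equal(p$distance, 1L)
  # breaking excludes more abundant partners of a low-abundance query
  ib <- which(ids(x) == "b")
  pb <- findPartners(x, ib, cfg)
  expect_false("a" %in% ids(x)[pb$index])
  cfgOff <- swarmConfig(t = 1, breaking = FALSE)
  pb2 <- findPartners(x, ib, cfgOff)
  expect_true("a" %in% ids(x)[pb2$index])
})

test_that("iterative growth reproduces the two-OTU worked example", {
  x <- poolOf(c("A", "B", "C", "D", "E"),
              c("AAAA", "AAAT", "AATT", "GGGG", "GGGC"),
              c(10L, 5L, 3L, 8L, 2L))
  r <- clusterPool(x, swarmConfig(t = 1))
  m <- otuMembers(r)
  expect_equal(m$id, c("A", "B", "C", "D", "E"))
  expect_equal(m$otu, c(1L, 1L, 1L, 2L, 2L))
  expect_equal(m$parent, c(NA, "A", "B", NA, "D"))
  expect_equal(m$generation, c(0L, 1L, 2L, 0L, 1L))
})

test_that("the breaking rule blocks chains at rising abundance", {
  x <- poolOf(c("A", "B", "C"), c("AAAA", "AAAT", "AATT"), c(10L, 2L, 5L))
  r <- clusterPool(x, swarmConfig(t = 1))
  expect_equal(nOtu(r), 2L)                       # C blocked at B (2 < 5)
  expect_equal(unname(otuAssignments(r)[c("A", "B")]), c(1L, 1L))
  expect_equal(unname(otuAssignments(r)["C"]), 2L)
  rOff <- clusterPool(x, swarmConfig(t = 1, breaking = FALSE))
  expect_equal(nOtu(rOff), 1L)
})

test_that("mutually distant singletons each seed their own OTU in priority order", {
  x <- poolOf(c("a", "b", "c"), c("AAAAAA", "TTTTTT", "CCCCCC"),
              c(3L, 9L, 5L))
  r <- clusterPool(x, swarmConfig(t = 1))
  m <- otuMembers(r)
  expect_equal(m$id, c("b", "c", "a"))
  expect_equal(m$otu, 1:3)
})

test_that("clustering equals the brute-force oracle on random fixtures", {
  for (seed in c(101, 202)) {
    cm <- testCommunity(seed, nSpecies = 6L, meanlog = log(15), length = 80L,
                        mutationRate = 0.01)
    x <- sortAmplicons(amplicons(cm))
    D <- oracleEditMatrix(sequences(x))
    for (t in c(1L, 2L)) {
      for (breaking in c(TRUE, FALSE)) {
        r <- clusterAmplicons(x, swarmConfig(t = t, breaking = breaking))
        o <- bruteForceClusters(abundances(x), t, breaking, D)
        m <- otuMembers(r)
        expect_equal(m$id, ids(x)[o$attach])
        expect_equal(m$otu, o$otu[o$attach])
        expect_equal(m$parent, ifelse(is.na(o$parent[o$attach]), NA,
                                      ids(x)[o$parent[o$attach]]))
        expect_equal(m$generation, o$generation[o$attach])
      }
    }
  }
})

test_that("OTUs partition the pool and seeds dominate with breaking on", {
  cm <- testCommunity(303, nSpecies = 5L)
  x <- sortAmplicons(amplicons(cm))
  r <- clusterAmplicons(x, swarmConfig(t = 2))
  m <- otuMembers(r)
  expect_setequal(m$id, ids(x))
  expect_equal(sum(otuWeights(r)), sum(abundances(x)))
  ab <- setNames(abundances(x), ids(x))
  for (blk in split(m, m$otu))
    expect_equal(unname(ab[blk$id[1L]]), max(ab[blk$id]))
  # every link distance is at most t
  expect_true(all(m$distance[!is.na(m$distance)] <= 2L))
})

test_that("input record order does not affect the result", {
  cm <- testCommunity(404, nSpecies = 4L)
  x <- amplicons(cm)
  set.seed(1)
  perm <- sample(length(x))
  shuffled <- AmpliconSet(ids = ids(x)[perm], sequences = sequences(x)[perm],
                          abundances = abundances(x)[perm],
                          inputRanks = seq_along(perm) - 1L)
  cfg <- swarmConfig(t = 2, fastidious = TRUE, tf = 4L)
  r1 <- clusterAmplicons(x, cfg)
  r2 <- clusterAmplicons(shuffled, cfg)
  expect_equal(otuMembers(r1), otuMembers(r2))
})

test_that("score mode clusters with alignment-difference edge weights", {
  x <- poolOf(c("a", "b", "c"), c("AAAAGGGG", "AAAGGGG", "AAAATTGG"),
              c(9L, 4L, 2L))
  r <- clusterPool(x, swarmConfig(t = 2, mode = "score"))
  m <- otuMembers(r)
  expect_equal(m$otu, c(1L, 1L, 1L))
  expect_equal(m$distance, c(NA, 1L, 2L))
})
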