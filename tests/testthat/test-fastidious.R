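ampSet <- function(ids, seqs, ab)
  AmpliconSet(ids = ids, sequences = seqs, abundances = ab)

test_that("light/heavy split follows the weight boundary", {
  a <- ampSet(c("a", "b", "c"), c("AAAAAA", "TTTTTT", "CCCCCC"),
              c(10L, 3L, 2L))
  r <- clusterAmplicons(a, swarmConfig(t = 1))
  lh <- splitLightHeavy(r, b = 3L)
  w <- otuWeights(r)
  expect_setequal(w[as.character(lh$heavy)], c(10L, 3L))
  expect_equal(unname(w[as.character(lh$light)]), 2L)
  expect_length(splitLightHeavy(r, b = 1L)$light, 0L)     # weights are >= 1
  expect_length(splitLightHeavy(r, b = 100L)$heavy, 0L)
})

test_that("each light amplicon keeps only its most abundant heavy partner", {
  light <- ampSet("l", "CCCC", 1L)
  heavy <- ampSet(c("h1", "h2"), c("CCCA", "CCCG"), c(10L, 7L))
  links <- enumerateGraftingLinks(light, heavy, tf = 2L, swarmConfig(t = 1))
  expect_equal(nrow(links), 1L)
  expect_equal(links$heavy, "h1")
  # no pair within tf: empty result
  far <- enumerateGraftingLinks(ampSet("l", "GGGGGGGG", 1L), heavy, tf = 2L,
                                swarmConfig(t = 1))
  expect_equal(nrow(far), 0L)
})

test_that("a virtual linking amplicon bridges two steps of one edit", {
  light <- ampSet("l", "CCCC", 1L)
  heavy <- ampSet("h", "CCAA", 5L)
  links <- enumerateGraftingLinks(light, heavy, tf = 2L, swarmConfig(t = 1))
  expect_equal(links$distance, 2L)  # via virtual intermediate "CCCA"
})

test_that("links are ordered by heavy then light abundance with id tie-breaks", {
  links <- data.frame(heavy = c("h5", "h5", "h9"), light = c("l1", "l3", "l1"),
                      distance = c(1L, 1L, 1L),
                      heavyAbundance = c(5L, 5L, 9L),
                      lightAbundance = c(1L, 3L, 1L), stringsAsFactors = FALSE)
  s <- sortGraftingLinks(links)
  expect_equal(paste(s$heavy, s$light), c("h9 l1", "h5 l3", "h5 l1"))
  expect_equal(sortGraftingLinks(s), s)
  tie <- data.frame(heavy = c("hb", "ha"), light = c("lz", "la"),
                    distance = c(1L, 1L), heavyAbundance = c(4L, 4L),
                    lightAbundance = c(2L, 2L), stringsAsFactors = FALSE)
  expect_equal(sortGraftingLinks(tie)$heavy, c("ha", "hb"))
})

# fixture with one heavy OTU and two light OTUs, both within tf of the heavy
graftFixture <- function() {
  ampSet(c("h1", "h2", "p", "q"),
         c("AAAAAAAA", "AAAAAAAT", "AAAAAAGG", "AATTAAAA"),
         c(20L, 6L, 2L, 1L))
}

test_that("multiple light OTUs graft onto one heavy OTU; V_d semantics hold", {
  a <- graftFixture()
  cfg <- swarmConfig(t = 1, fastidious = TRUE, tf = 2L, boundary = 3L)
  base <- clusterAmplicons(a, swarmConfig(t = 1))
  expect_equal(nOtu(base), 3L)
  r <- clusterAmplicons(a, cfg)
  expect_equal(nOtu(r), 1L)
  expect_equal(nrow(graftingRecords(r)), 2L)
  expect_equal(sum(otuWeights(r)), sum(abundances(a)))  # weight conservation

  # literal evaluation of the valid-link set: scan sorted potential links,
  # keep a link iff no earlier kept link grafted the same light OTU
  lh <- splitLightHeavy(base, 3L)
  mm <- otuMembers(base)
  lightIds <- mm$id[mm$otu %in% lh$light]
  heavyIds <- mm$id[mm$otu %in% lh$heavy]
  seqs <- setNames(sequences(a), ids(a))
  ab <- setNames(abundances(a), ids(a))
  pot <- expand.grid(h = heavyIds, l = lightIds, stringsAsFactors = FALSE)
  pot$d <- mapply(function(h, l) oracleEdit(seqs[[h]], seqs[[l]]), pot$h, pot$l)
  pot <- pot[pot$d <= 2L, ]
  # reduce to the most abundant heavy partner per light amplicon
  pot <- pot[order(pot$l, -ab[pot$h], pot$h), ]
  pot <- pot[!duplicated(pot$l), ]
  pot <- pot[order(-ab[pot$h], -ab[pot$l], pot$h, pot$l), ]
  otuOfLight <- setNames(mm$otu, mm$id)[pot$l]
  valid <- !duplicated(otuOfLight)
  expected <- pot[valid, ]
  got <- graftingRecords(r)
  expect_equal(got$heavy, expected$h)
  expect_equal(got$light, expected$l)
  expect_equal(got$distance, as.integer(expected$d))
})

test_that("a light OTU is grafted at most once even with several heavy partners", {
  a <- ampSet(c("h1", "h2", "l"),
              c("CCCCCCAA", "CCCCCCTT", "CCCCCCGG"),
              c(9L, 8L, 1L))
  # l is within tf = 2 of both heavy seeds, which form two separate OTUs
  r <- clusterAmplicons(a, swarmConfig(t = 1, fastidious = TRUE, tf = 2L,
                                       boundary = 3L))
  expect_equal(nrow(graftingRecords(r)), 1L)
  expect_equal(graftingRecords(r)$heavy, "h1")  # higher heavy abundance wins
  expect_equal(nOtu(r), 2L)
})

test_that("grafted members are re-rooted beneath the linking amplicon", {
  a <- ampSet(c("h", "l1", "l2"), c("AAAAAAAA", "AAAAAAGG", "AAAAATGG"),
              c(10L, 1L, 1L))
  # light OTU {l1, l2} (weight 2): l1 links to h at distance 2
  r <- clusterAmplicons(a, swarmConfig(t = 1, fastidious = TRUE, tf = 2L,
                                       boundary = 3L))
  m <- otuMembers(r)
  expect_equal(m$id, c("h", "l1", "l2"))
  expect_equal(m$parent, c(NA, "h", "l1"))
  expect_equal(m$distance, c(NA, 2L, 1L))
  expect_equal(m$generation, c(0L, 1L, 2L))
  expect_equal(m$grafted, c(FALSE, TRUE, FALSE))
  lines <- otuInternalLines(r)
  expect_true("h\tl1\t2\t1\t1\tG" %in% lines)   # graft link flagged
  expect_true("l1\tl2\t1\t1\t2" %in% lines)     # intra-light link unflagged
})

test_that("fastidious with b = 1 or no qualifying pairs is a no-op", {
  a <- graftFixture()
  plain <- clusterAmplicons(a, swarmConfig(t = 1))
  b1 <- clusterAmplicons(a, swarmConfig(t = 1, fastidious = TRUE, tf = 2L,
                                        boundary = 1L))
  expect_equal(otuMembers(b1), otuMembers(plain))
  expect_equal(nrow(graftingRecords(b1)), 0L)
  far <- ampSet(c("h", "l"), c("AAAAAAAA", "TTTTTTTT"), c(9L, 1L))
  rFar <- clusterAmplicons(far, swarmConfig(t = 1, fastidious = TRUE, tf = 2L,
                                            boundary = 3L))
  expect_equal(nOtu(rFar), 2L)
})

test_that("potential links at tf = t + 1 nest inside links at tf = 2t", {
  set.seed(59)
  t <- 2L
  centro <- randSeq(60)
  seqs <- unique(c(centro, vapply(1:40, function(i)
    applyEdits(centro, sample(1:4, 1L)), "")))
  half <- seq_len(floor(length(seqs) / 2))
  light <- seqs[half]
  heavy <- seqs[-half]
  raw3 <- ampliswarm:::cpp_graft_links(light, heavy, t + 1L, 2L, 0L,
                                       defaultScoring())
  raw4 <- ampliswarm:::cpp_graft_links(light, heavy, 2L * t, 2L, 0L,
                                       defaultScoring())
  key3 <- paste(raw3[, 1], raw3[, 2])
  key4 <- paste(raw4[, 1], raw4[, 2])
  expect_true(all(key3 %in% key4))
  expect_gte(nrow(raw4), nrow(raw3))
})
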