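test_that("even partition tiles the sequence with longer segments last", {
  expect_equal(unname(segmentPartition(10, 3)),
               matrix(c(0L, 3L, 6L, 3L, 3L, 4L), ncol = 2))
  expect_equal(unname(segmentPartition(9, 3)),
               matrix(c(0L, 3L, 6L, 3L, 3L, 3L), ncol = 2))
  expect_error(segmentPartition(2, 3), "shorter")
  # property: tiling and near-even lengths for assorted (l, n)
  for (l in c(7L, 20L, 33L)) {
    for (n in c(1L, 2L, 5L, 7L)) {
      p <- segmentPartition(l, n)
      expect_equal(unname(p[, "start"]),
                   unname(cumsum(c(0L, head(p[, "length"], -1L)))))
      expect_equal(sum(p[, "length"]), l)
      expect_lte(diff(range(p[, "length"])), 1L)
    }
  }
})

test_that("multimatch-aware windows match the worked positions", {
  expect_equal(selectSubstrings(10, 10, i = 2, p = 3, li = 3, tau = 2), 2:4)
  expect_equal(selectSubstrings(10, 10, i = 1, p = 0, li = 3, tau = 2), 0L)
  expect_equal(selectSubstrings(10, 10, i = 3, p = 6, li = 4, tau = 2), 6L)
})

test_that("multimatch windows are complete over all low-distance neighbours", {
  # for every string S within tau edits of R, some selected substring of S
  # must equal the corresponding segment of R for at least one i
  set.seed(5)
  tau <- 2L
  R <- randSeq(12)
  part <- segmentPartition(nchar(R), tau + 1L)
  for (z in 1:200) {
    S <- applyEdits(R, sample(0:tau, 1L))
    if (ampliswarm:::cpp_naive_edit(R, S) > tau) next
    hit <- FALSE
    for (i in seq_len(nrow(part))) {
      seg <- substr(R, part[i, 1] + 1L, part[i, 1] + part[i, 2])
      ws <- selectSubstrings(nchar(S), nchar(R), i, part[i, 1], part[i, 2], tau)
      if (any(vapply(ws, function(w)
            substr(S, w + 1L, w + part[i, 2]) == seg, NA))) hit <- TRUE
    }
    expect_true(hit)
  }
})

test_that("candidate generation finds shared segments and rejects disjoint sequences", {
  pool <- c("AAAACCCC")
  expect_equal(segmentCandidates("AAAACCCG", pool, tau = 1, k = 1), 1L)
  expect_length(segmentCandidates("TTTTGGGG", pool, tau = 1, k = 1), 0L)
  # self exclusion
  expect_length(segmentCandidates("AAAACCCC", pool, tau = 1, k = 1, self = 1L), 0L)
})

test_that("filter pipeline is complete for mutated pairs (property)", {
  set.seed(17)
  for (z in 1:300) {
    t <- sample(1:3, 1L)
    k <- sample(1:2, 1L)
    R <- randSeq(60)
    S <- applyEdits(R, sample(0:t, 1L))
    d <- ampliswarm:::cpp_naive_edit(R, S)
    if (d > t || S == R) next
    expect_true(1L %in% segmentCandidates(S, R, tau = t, k = k))
    expect_true(bidirectionalCheck(S, R, tau = t, k = k))
    expect_true(bidirectionalCheck(R, S, tau = t, k = k))
  }
})

test_that("bidirectional check rejects clearly distant pairs", {
  expect_false(bidirectionalCheck("AAAAAAAA", "TTTTTTTT", tau = 1, k = 1))
})

test_that("candidate sets are monotone in tau and antitone in k", {
  set.seed(23)
  pool <- vapply(rep(40, 60), randSeq, "")
  pool <- c(pool, vapply(pool[1:20], applyEdits, "", nEdits = 2))
  q <- applyEdits(pool[1], 1)
  for (tau in 1:3) {
    lo <- segmentCandidates(q, pool, tau = tau, k = 1)
    hi <- segmentCandidates(q, pool, tau = tau + 1L, k = 1)
    expect_true(all(lo %in% hi))
    k2 <- segmentCandidates(q, pool, tau = tau, k = 2)
    expect_true(all(k2 %in% lo))
  }
})

test_that("amplicons too short to partition bypass the filter", {
  pool <- c("ACGTACGTAC", "ACG")  # second is shorter than tau + k segments
  got <- segmentCandidates("ACGG", pool, tau = 2, k = 2)
  expect_true(2L %in% got)   # length-compatible short amplicon is returned
  expect_false(1L %in% got)  # length difference 6 > tau
})
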