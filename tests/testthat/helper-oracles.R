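# Independent reference implementations used as oracles throughout the
# suite. None of them share code with the package's engine: edit distances
# come from a naive unbanded full DP (cross-validated against utils::adist),
# clustering from a literal breadth-first re-implementation of the iterative
# strategy on a precomputed distance matrix, and affine-gap alignment from a
# plain unbanded R Gotoh DP validated against exhaustive alignment
# enumeration on tiny strings.

oracleEdit <- function(a, b) ampliswarm:::cpp_naive_edit(a, b)

oracleEditMatrix <- function(seqs) ampliswarm:::cpp_naive_edit_matrix(seqs)

# literal iterative clustering: abundance-ranked seeds, breadth-first
# generations, first claim wins, optional breaking rule; no filtering, all
# distances taken from the full matrix D
bruteForceClusters <- function(ab, t, breaking, D) {
  N <- length(ab)
  otu <- rep(NA_integer_, N)
  parent <- rep(NA_integer_, N)
  dist <- rep(NA_integer_, N)
  gen <- rep(0L, N)
  attach <- integer(0)
  nOtu <- 0L
  for (s in seq_len(N)) {            # inputs arrive in priority order
    if (!is.na(otu[s])) next
    nOtu <- nOtu + 1L
    otu[s] <- nOtu
    attach <- c(attach, s)
    cur <- s
    while (length(cur) > 0L) {
      nxt <- integer(0)
      for (a in sort(cur)) {         # subseeds in global priority order
        part <- which(is.na(otu) & D[a, ] <= t)
        if (breaking) part <- part[ab[part] <= ab[a]]
        for (b in sort(part)) {
          if (!is.na(otu[b])) next
          otu[b] <- nOtu
          parent[b] <- a
          dist[b] <- D[a, b]
          gen[b] <- gen[a] + 1L
          attach <- c(attach, b)
          nxt <- c(nxt, b)
        }
      }
      cur <- nxt
    }
  }
  list(otu = otu, parent = parent, distance = dist, generation = gen,
       attach = attach, nOtu = nOtu)
}

# unbanded Gotoh DP with the same objective as the engine claims: maximise
# score, then minimise difference columns, then minimise aligned columns;
# gap of length g costs open + g * extend
lexBetter <- function(x, y) {
  if (x[1] != y[1]) return(x[1] > y[1])
  if (x[2] != y[2]) return(x[2] < y[2])
  x[3] < y[3]
}
lexBest <- function(x, y) if (lexBetter(x, y)) x else y

gotohOracle <- function(a, b, delta = c(5, 4, 12, 4)) {
  mt <- delta[1]; mm <- delta[2]; go <- delta[3]; ge <- delta[4]
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  NEG <- -1e9
  bad <- c(NEG, 0, 0)
  M <- X <- Y <- array(rep(bad, each = (m + 1) * (n + 1)),
                       dim = c(m + 1, n + 1, 3))
  M[1, 1, ] <- c(0, 0, 0)
  for (i in seq_len(m)) X[i + 1, 1, ] <- c(-go - ge * i, i, i)
  for (j in seq_len(n)) Y[1, j + 1, ] <- c(-go - ge * j, j, j)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      d <- lexBest(lexBest(M[i, j, ], X[i, j, ]), Y[i, j, ])
      if (d[1] > NEG / 2) {
        eq <- A[i] == B[j]
        M[i + 1, j + 1, ] <- d + c(if (eq) mt else -mm, if (eq) 0 else 1, 1)
      }
      x <- bad
      if (M[i, j + 1, 1] > NEG / 2) x <- lexBest(x, M[i, j + 1, ] + c(-go - ge, 1, 1))
      if (X[i, j + 1, 1] > NEG / 2) x <- lexBest(x, X[i, j + 1, ] + c(-ge, 1, 1))
      if (Y[i, j + 1, 1] > NEG / 2) x <- lexBest(x, Y[i, j + 1, ] + c(-go - ge, 1, 1))
      X[i + 1, j + 1, ] <- x
      y <- bad
      if (M[i + 1, j, 1] > NEG / 2) y <- lexBest(y, M[i + 1, j, ] + c(-go - ge, 1, 1))
      if (Y[i + 1, j, 1] > NEG / 2) y <- lexBest(y, Y[i + 1, j, ] + c(-ge, 1, 1))
      if (X[i + 1, j, 1] > NEG / 2) y <- lexBest(y, X[i + 1, j, ] + c(-go - ge, 1, 1))
      Y[i + 1, j + 1, ] <- y
    }
  }
  fin <- lexBest(lexBest(M[m + 1, n + 1, ], X[m + 1, n + 1, ]),
                 Y[m + 1, n + 1, ])
  c(score = fin[1], diffs = fin[2], cols = fin[3])
}

# exhaustive enumeration of every global alignment of two (tiny) strings,
# returning the lexicographically best (score, diffs, cols) triple
enumOracle <- function(a, b, delta = c(5, 4, 12, 4)) {
  mt <- delta[1]; mm <- delta[2]; go <- delta[3]; ge <- delta[4]
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  best <- c(-Inf, Inf, Inf)
  rec <- function(i, j, state, score, diffs, cols) {
    # state: move made immediately to the right (0 none/diag, 1 gap in b,
    # 2 gap in a); a gap extends iff the right neighbour is the same gap type
    if (i == 0 && j == 0) {
      v <- c(score, diffs, cols)
      if (lexBetter(v, best)) best <<- v
      return(invisible(NULL))
    }
    if (i > 0 && j > 0) {
      eq <- A[i] == B[j]
      rec(i - 1, j - 1, 0, score + if (eq) mt else -mm,
          diffs + if (eq) 0 else 1, cols + 1)
    }
    if (i > 0)
      rec(i - 1, j, 1, score - ge - if (state == 1) 0 else go, diffs + 1,
          cols + 1)
    if (j > 0)
      rec(i, j - 1, 2, score - ge - if (state == 2) 0 else go, diffs + 1,
          cols + 1)
  }
  rec(length(A), length(B), 0L, 0, 0, 0)
  c(score = best[1], diffs = best[2], cols = best[3])
}

# random DNA and controlled mutants for property-style tests
randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

applyEdits <- function(s, nEdits) {
  for (z in seq_len(nEdits)) {
    ch <- strsplit(s, "")[[1]]
    op <- sample(3L, 1L)
    p <- sample(length(ch), 1L)
    if (op == 1L) ch[p] <- sample(c("A", "C", "G", "T"), 1L)
    else if (op == 2L && length(ch) > 1L) ch <- ch[-p]
    else ch <- append(ch, sample(c("A", "C", "G", "T"), 1L), after = p)
    s <- paste(ch, collapse = "")
  }
  s
}

# mock community scaled for oracle-checked tests
testCommunity <- function(seed, nSpecies = 8L, meanlog = log(25),
                          length = 150L, mutationRate = 0.005) {
  generateCommunity(nSpecies = nSpecies, readsMeanlog = meanlog,
                    readsSdlog = 0.8, mutationRate = mutationRate,
                    indelFraction = 0.15, length = length, separation = 10L,
                    seed = seed)
}
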