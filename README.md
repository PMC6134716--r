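# ampliswarm

Exact, alignment-based de novo clustering of amplicons into OTUs, in R.

Microbial community studies routinely sequence millions of 16S rRNA gene
fragments and group the dereplicated amplicons into operational taxonomic
units (OTUs) before any diversity analysis. Classic de novo clustering with
a fixed global identity threshold is sensitive to input order and to the
choice of threshold. `ampliswarm` implements the iterative, seed-based
alternative: OTUs grow outwards from the most abundant amplicons using a
small *local* threshold `t`, stop at their natural boundaries, and can be
refined by a *fastidious* step that rescues low-abundance clusters —
generalised here to arbitrary `t` and an independent fastidious threshold
`t_f`.

## The method

An OTU is a rooted, acyclic, edge-weighted member graph `G = (V, E, s, w)`:
the seed `s` is the most abundant unassigned amplicon, and each generation
attaches every unassigned amplicon within distance `d(a, b) <= t` of a
current member. The distance is either the plain edit distance `d_e` or, in
scoring-function mode, `d_delta` — the number of difference columns
(mismatches plus gap columns) in an optimal affine-gap alignment under a
scoring function `delta` (default match 5, mismatch 4, gap opening 12, gap
extension 4). With the breaking rule (default on), links must satisfy
`a.abundance >= b.abundance` outwards from the seed, so distinct centres of
abundance become separate OTUs instead of chaining together.

The fastidious refinement splits OTUs at a weight boundary `b` (total
abundance; default 3) into light (`< b`) and heavy (`>= b`). A light OTU is
grafted onto a heavy one when an amplicon pair `(h, l)` bridges them within
`t_f` (default `2t`, conceptually via a virtual linking amplicon); each
light amplicon keeps only its most abundant heavy partner, links are applied
in decreasing (heavy, light) abundance order, and every light OTU is
grafted at most once.

Finding partner candidates is the expensive step, and it is done with a
pigeonhole segment filter: every sequence is cut into `tau + k` even
segments, of which at least `k` must occur — at admissible, multimatch-aware
positions — in any sequence within distance `tau`. Inverted indices over the
segments yield the candidates, a bidirectional second stage with swapped
roles prunes them further, and survivors are confirmed by bounded,
length-aware verification (banded DP with early termination; a banded Gotoh
recurrence in scoring-function mode). Amplicons whose lengths differ by more
than `tau` can never be similar, so the input is first split into
independent length pools.

## A worked example

```r
library(ampliswarm)

a <- AmpliconSet(ids        = c("a", "b", "c", "d", "e"),
                 sequences  = c("AAAA", "AAAT", "AATT", "GGGG", "GGGC"),
                 abundances = c(10L, 5L, 3L, 8L, 2L))
r <- clusterAmplicons(a, swarmConfig(t = 1))
otuMembershipLines(r)
#>              1              2
#> "a_10 b_5 c_3"      "d_8 e_2"
otuStatisticsLines(r)
#> [1] "3\t18\ta\t10\t0\t2\t2" "2\t10\td\t8\t0\t1\t1"
```

Amplicon `a` (abundance 10) seeds the first OTU, attaches `b` at distance 1
(generation 1), and `b` attaches `c` (generation 2); `d` and `e` form a
second OTU. The statistics line per OTU reports: unique amplicons, total
abundance, seed id, seed abundance, members with abundance 1, maximum
generation, and maximum summed link distance from the seed.

The same pipeline is available from a shell via the installed `exec` script:

```sh
ampliswarm simulate --seed 1 --fasta mock.fasta --truth truth.tsv
ampliswarm cluster mock.fasta -t 1 -f -o members.txt -s stats.tsv
ampliswarm evaluate --membership members.txt --truth truth.tsv
```

`simulate` builds a mock community of known composition (log-normal species
abundances, point mutations and indels on species centroids) and `evaluate`
scores any membership file with pair-counting precision and recall and the
adjusted Rand index.

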