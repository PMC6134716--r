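---
title: "Iterative OTU clustering with a generalised fastidious refinement"
author: "ampliswarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative OTU clustering with a generalised fastidious refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliswarm)
```

## The clustering model

`ampliswarm` clusters dereplicated amplicons (unique sequences carrying a
read-count abundance) into OTUs by iterative growth rather than by a fixed
global identity cutoff. An OTU is a rooted, acyclic member graph: the seed
is the most abundant unassigned amplicon; each breadth-first generation
attaches every still-unassigned amplicon within distance $d(a,b) \le t$ of a
current member, with the link weight set to the verified distance. The OTU
closes when a generation stays empty, and the next seed starts a new OTU.
Because $t$ is local — it constrains single links, not the OTU diameter —
clusters find their natural extent, and because seeds are chosen by
abundance the result is independent of input record order.

Two distances are supported. In **edit-distance mode** $d = d_e$, the
Levenshtein distance. In **scoring-function mode** $d = d_\delta$, the
number of difference columns (mismatches plus gap columns) in a global
alignment that is optimal under an affine scoring function
$\delta =$ (match reward, mismatch penalty, gap opening, gap extension),
default $(5, 4, 12, 4)$. A gap of length $g$ costs $open + g \cdot extend$,
i.e. the extension is charged for every gap column including the first;
this convention must be fixed because tools differ, and it is stated here
once and used everywhere.

The optional **breaking** rule (default on) admits a link $a \to b$ only if
$a.abundance \ge b.abundance$. Walking outwards from the seed, abundances
can then never rise, so two centres of abundance connected by a valley of
rare amplicons split into separate OTUs — the main defence against
single-linkage chaining. The $\ge$ (rather than $>$) deliberately lets
plateaus of equal abundance chain indefinitely.

## Fastidious refinement

Low-abundance OTUs are often fragments of a larger cluster that one more
mutation step would have joined. The refinement therefore splits OTUs at a
weight boundary $b$ (total member abundance, default 3) into light
($< b$) and heavy ($\ge b$) and grafts light OTUs onto heavy ones: a pair
$(h, l)$ of a heavy and a light amplicon with $d(h, l) \le t_f$ justifies
moving the entire light OTU into the heavy one, as if a virtual linking
amplicon sat between them. The virtual amplicon itself is never added.

The step is generalised in two ways: it works for any clustering threshold
$t$, and $t_f$ is freely adjustable with default $t_f = 2t$ (a virtual
amplicon within $t$ of both sides); $t_f = t + 1$ is the conservative
alternative, and any $t_f \ge t + 1$ is accepted. For each light amplicon
only the most abundant heavy partner is kept; links are applied in
decreasing heavy abundance, then decreasing light abundance; and a light
OTU is grafted at most once. Remaining ties (equal abundances) are broken
by id so the order is total and the output deterministic.

After a graft the light OTU's member graph is re-rooted at the linking
amplicon $l$: $l$ becomes a child of $h$ with the link distance as weight
and generation $gen(h) + 1$, and the light OTU's own edges are kept but
re-oriented away from $l$. This was a genuinely open design point — only
the set of moved amplicons is forced by the definitions — and re-rooting
was chosen because it keeps every output well-defined (generations, radii
and the link table stay consistent) while preserving the recorded edges.
In the link-structure output the graft link carries a trailing `G` flag;
the light OTU's internal links stay unflagged.

## Finding candidate pairs: the segment filter

All partner searches run through a pigeonhole segment filter. For threshold
$\tau$ ($t$ during clustering, $t_f$ during refinement) every sequence is
cut into $\tau + k$ contiguous segments whose lengths differ by at most one
(longer segments last — any fixed layout works, but index and query must
agree). If $d(S, R) \le \tau$, at most $\tau$ segments of $R$ can be
touched by edits, so at least $k$ occur verbatim in $S$. Inverted indices
$I_{l,i}$ map (sequence length, segment index, segment string) to the
amplicons containing that segment, and are built once per pool since
amplicons are processed by abundance, not length.

Queries do not scan all substrings: for $k = 1$ the multimatch-aware
window of the Pass-Join family is used, which combines the segment position
with the length difference $\Delta = |S| - l$ to bound admissible start
positions. For $k > 1$ the tight generalised window is not reproduced in
the literature we follow, so a conservative $\pm\tau$ window is used —
completeness over tightness; the bidirectional second stage (roles of the
pair swapped, again $\ge k$ matches required) recovers most of the lost
filtering power. Amplicons shorter than $\tau + k$ cannot be partitioned;
they are kept in a side list and verified directly against all
length-compatible queries. In scoring-function mode the same edit-distance
filter applies unchanged, because the difference count of any alignment is
bounded below by the edit distance.

## Bounded verification

Surviving candidates are verified by banded dynamic programming over the
$2\tau + 1$ diagonals around the main diagonal — any alignment with at most
$\tau$ differences deviates at most $\tau$ — with early termination once a
whole row exceeds $\tau$, and an immediate reject when $|\Delta| > \tau$.
In scoring-function mode the same band restricts Gotoh's three-state
affine recurrence.

One numerical convention deserves a note: when several alignments share
the optimal score, their difference counts can differ. `ampliswarm`
defines $d_\delta$ as the *minimum* difference count among optimal-score
alignments, carried through the DP as a lexicographic objective
(maximise score, then minimise differences, then minimise columns). This
is deterministic, independent of traceback order, and stable under
banding: any alignment with $\le \tau$ differences lies inside the band,
so the banded optimum coincides with the unrestricted one whenever the
answer is within the bound. A canonical-traceback definition (preferring
diagonal moves) was considered and rejected because its value can depend
on which co-optimal path the traceback happens to visit at the band edge.

## Pooling

Since $d_e(a,b) \ge ||a| - |b||$, and any alignment of sequences with
length gap $g$ contains at least $g$ gap columns, amplicons whose lengths
differ by more than $t$ can never link. The sorted distinct lengths are cut
into maximal runs with consecutive gaps $\le t$; each run is an independent
pool, clustered separately with OTUs renumbered afterwards by the global
priority of their seeds, which makes pooling invisible in the output. The
same argument holds in scoring-function mode, so pooling applies in both.

## Determinism

Every ordering in the pipeline is total: amplicons are ranked by abundance
descending, then id (C locale), then input rank; subseeds are processed in
that priority order within each generation; when two subseeds of one
generation both reach an amplicon, the one processed earlier claims it;
grafting ties fall back to ids. Shuffling the input records changes
nothing, byte for byte, in any of the five output files.

## The mock-community generator

`generateCommunity()` emulates a dereplicated mock community: `nSpecies`
random centroids (default 20) with pairwise edit distance at least
`separation` (default 10, so species stay resolvable at small $t$), species
total read counts drawn log-normally (`readsMeanlog = log(200)`,
`readsSdlog = 1` — a few abundant and many rare species, as in skewed
real communities), and reads that are centroid copies with independent
per-base mutations (`mutationRate = 0.002`, in the range of typical
amplicon pipeline error rates; `indelFraction = 0.1` of mutations are
indels, half insertions, half deletions; default read length 250 bp,
matching common 16S V4 amplicons). Identical reads are dereplicated with
summed abundance and every unique amplicon keeps its species label. The
generator is fully reproducible from its seed.

It does **not** emulate chimeras, position- or homopolymer-dependent error
profiles, primer/length heterogeneity beyond mutation indels, or shared
sequences between species (collisions are resolved to the more abundant
origin and are practically absent at the default separation). Passing
tests on these communities therefore demonstrates algorithmic correctness
— the filter misses no pair, clustering equals the brute-force definition,
refinement follows the grafting rules — not field performance on real
survey data, where error structure and taxon overlap are harsher.

## Evaluation metrics

Clusterings are scored against the ground truth over unordered amplicon
pairs: recall (same-species pairs co-clustered), precision (co-clustered
pairs same-species), and the Hubert–Arabie adjusted Rand index from the
predicted-by-truth contingency table. Empty denominators score 1.0 (an
all-singleton prediction asserts no pairs, so none are wrong). Metrics are
computed over unique amplicons, unweighted; an abundance-weighted variant
is available via the `weights` argument of `pairCountingMetrics()` but is
not used in any shipped check.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on generated data,
at sizes chosen so that the brute-force references (full unbanded DP over
all pairs, literal breadth-first clustering) remain exact and affordable:
filter completeness on twenty communities of up to 500 unique amplicons
with lengths 150–300 at $\tau \in \{1,2,3,4,6\}$ and $k \in \{1,2\}$;
verification equivalence on $10^4$ random pairs (lengths 20–80, up to 6
edits) plus $10^3$ short pairs for the affine mode; clustering equivalence
on ten fixtures of up to 300 amplicons for $t \in \{1,2,3\}$ with breaking
on and off. These sizes exercise every code path (multiple pools,
multi-generation OTUs, short-amplicon fallback, grafting chains) while
keeping the references trustworthy.

## Known limitations

* Runtime grows with $\tau$: the number of admissible substrings per
  segment grows with the window width, and more inverted indices are
  needed; large thresholds ($t \gtrsim 10$) are better served by classic
  global-threshold tools.
* The $k > 1$ windows are conservative; a tight generalised multimatch
  bound would filter harder.
* Scoring-function mode guarantees completeness relative to the edit
  filter ($d_\delta \ge d_e$), but a pathological $\delta$ that makes long
  gaps cheaper than mismatches could in principle make the banded optimum
  differ from the unrestricted one outside the $\le \tau$ regime; with the
  default (and any reasonable) scoring this does not arise.
* Pools are processed sequentially; the per-pool independence would permit
  parallelism that is not implemented.
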