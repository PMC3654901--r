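---
title: "Greedy read clustering with an LCS filter: model, parameters, and design notes"
author: "lcsclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy read clustering with an LCS filter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcsclust)
```

## The clustering model

`lcsclust` partitions a set of DNA reads at a sequence-identity threshold
$s$ by greedy incremental assignment, the scheme made familiar by CD-HIT.
Reads are processed one at a time.  Each read $q$ either joins the cluster
of an existing representative $r$ with

$$\mathrm{identity}(q, r) \;=\; \frac{\text{matches in the score-optimal
affine-gap alignment}}{\min(|q|, |r|)} \;\ge\; s,$$

or founds a new cluster and becomes its representative.  Representatives
are never updated as members accrue, which is what makes the scheme fast —
each read is compared against representatives only — and also what makes
the result depend on the processing order.

The expensive step is the alignment, $O(mn)$ per pair.  Almost all pairs
are dissimilar, so the point of the method is to discard them *before*
aligning, through two cascaded filters:

1. **Short-word filter.**  Every *k*-th *k*-mer of each representative
   (default $k = 9$; positions $0, k, 2k, \dots$, plus the final window
   when the last stride does not land on the sequence end) is registered
   in a direct-address index of $4^k$ buckets.  A query enumerates *all*
   of its *k*-mers and keeps representatives sharing at least $t$ of them.
   Registering only a 1/k fraction of words keeps the table small; in
   exchange, $t$ must be low (default: 1 for reads up to 200 bases, 4
   above — roughly an all-word threshold divided by $k$).

2. **LCS filter.**  The length of the longest common subsequence,
   $\mathrm{LLCS}(q, r)$, equals the number of matches in the
   match-maximizing alignment, so for any pair
   $$\frac{\mathrm{LLCS}(q, r)}{\min(|q|, |r|)} \;\ge\; \mathrm{identity}(q, r).$$
   A candidate whose bound falls below $s$ cannot reach identity $s$ and
   is pruned with **no false negatives** — the filter reuses the
   threshold $s$ itself and needs no tuning of its own.  The cascade
   therefore never rejects, before alignment, a pair that alignment would
   have accepted.

Survivors are aligned (three-state Gotoh dynamic programming, affine gaps)
and the identity decides membership, boundary inclusive.

## The bit-parallel LLCS kernel

Computing LLCS by dynamic programming is itself $O(mn)$, which would defeat
the purpose.  The kernel instead packs the DP column state into machine
words.  `computePM()` builds, once per representative, a position mask per
base: bit $i$ of mask $b$ is set iff position $i+1$ of the representative
carries $b$ (cost $O(\sigma\lceil m/w\rceil + m)$, $\sigma = 4$).  Each
query symbol $c$ then advances all $m$ cells with word-wide operations

$$U = V \wedge \mathrm{PM}[c], \qquad V' = (V + U)\,\vee\,(V - U),$$

starting from an all-ones $V$; the LCS length is the number of cleared
bits among the low $m$ positions of the final $V$.  Cost is
$O(\sigma\lceil m/w\rceil\, n)$ — for 150-base reads and $w = 64$, three
words per operation instead of 150 DP cells.  When $m > w$ the addition
and subtraction propagate carries and borrows across adjacent blocks
explicitly; `wordWidth` can be lowered to 8/16/32 to exercise that
chaining (the tests do), but 64 is always the right production setting.
The kernel's contract is exact equality with the DP recurrence
(`llcsDP()`), which the test suite enforces on exhaustively sampled short
pairs and on long pairs spanning many blocks, with
`Biostrings::pairwiseAlignment` (zero gap cost, prohibitive mismatch) as a
third, independent route.

Positions holding N appear in no mask, so an N matches nothing — not even
another N.  An ambiguous base must never inflate an identity upper bound,
or the filter's no-false-negative guarantee would silently erode in the
other direction (admitting a pair is always safe; excluding one is not).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `s` | 0.9 | identity threshold (fraction of the shorter length); 0.9 is the conventional choice for read deduplication in metagenomics |
| `k` | 9 | word length of the prefilter; $4^9 = 262{,}144$ buckets |
| `t` | `"auto"` | common-word threshold; 1 for median read length ≤ 200, else 4 |
| `match/mismatch` | +2 / −2 | alignment scores |
| `gapOpen/gapExtend` | −6 / −1 | a gap of length $L$ costs $-6 - L$ |
| `endGapsFree` | `TRUE` | read overhangs cost nothing |
| `ordering` | `length_desc` | processing order; `input` preserves file order |
| `assignment` | `first` | first qualifying cluster; `best` takes the highest identity |

The alignment scores are a conventional nucleotide scheme and fully
configurable; only the identity *definition* (matches over the shorter
length) is fixed, because the LCS bound is a bound on exactly that
quantity.  Free end gaps are the natural partner of that denominator:
a 100-base read inside a 150-base representative can reach identity 1.

With mixed-length input, `t = "auto"` resolves through the median read
length — a run-level rule is needed where fixed-length datasets needed
none.

## Numerical and tie-break choices

* **Co-optimal alignments.**  Different score-optimal alignments can carry
  different match counts (an all-overhang "dovetail" of two unrelated
  reads scores 0, and so may a partially matched alignment).  The
  traceback prefers the match/mismatch state over gap states, and the
  pair is oriented canonically (shorter, then lexicographically smaller,
  sequence first) before the DP, so the reported identity is a
  deterministic *and symmetric* function of the pair.
* **LCS filter comparison** is `LLCS / n >= s` in double precision; the
  identity decision is likewise `identity >= s`, inclusive.
* **Degenerate reads.**  Reads shorter than `k`, and all-N reads (whose
  words are all skipped), can never pass the word filter; they found
  singleton clusters rather than erroring.
* **Representative-side word multiplicity** is ignored: a query position
  counts at most once per representative, which keeps the count monotone
  in `t` and cheap to maintain.

## The synthetic read generator

`generateReadSet()` emulates the cluster structure of a deduplication
workload: `nSeeds` uniform-random seed sequences, rejection-sampled until
all pairwise identities are at most `1 - minSeedDivergence` (default cap
0.8), each emitted with `readsPerSeed` mutated copies — per-base
substitutions at `subRate` (default 3%, a deliberately pessimistic error
rate for short reads) and insertions/deletions at `indelRate` (default
0.5%).  Labels record each read's seed, so recovery can be scored with the
adjusted Rand index without any external data.  Everything is reproducible
from one RNG seed.

What it does *not* emulate: genomic base composition and repeats,
position-dependent error profiles, homopolymer artifacts, chimeras, or
quality strings.  Passing tests therefore demonstrate the correctness of
the filters, the aligner and the greedy loop under known ground truth —
not that any particular biological dataset will cluster into neat groups.

One behaviour of the greedy scheme shows up clearly on this fixture and
is worth understanding: under `length_desc` ordering the representative
of a cluster is usually a *mutated copy*, not the seed.  Two copies at 3%
substitution sit near identity $0.94$ of each other (errors on both
sides), so with $s = 0.9$ an occasional member falls just short of the
representative and founds a spurious cluster.  Recovery of the default
20-seed fixture is therefore an ARI of roughly 0.98–1.0 depending on the
RNG seed, not always exactly 1 — a property of greedy fixed-representative
clustering itself, not of the filters, and the reason the acceptance
checks score recovery by ARI rather than by exact cluster count.

## Problem sizes used in the checks

The shipped verification runs at desk scale, chosen to finish in minutes
on one core: kernel cross-validation on 10,000 random pairs up to 320
bases (plus ~100,000 short pairs), filter soundness on 1,000 pairs at each
of $s \in \{0.8, 0.9, 0.95\}$, alignment-oracle equivalence on 10,000
pairs of length ≤ 5 against full enumeration over all alignments, and an
end-to-end run of 10,000 synthetic 150-base reads (500 clusters of 20).
Wall-clock benchmarking against other tools, and datasets in the millions
of reads, are out of scope.

## Known limitations

* Representatives are frozen at creation; there is no re-centering or
  second clustering pass, so cluster splits of the kind described above
  are inherent.
* The word filter can in principle miss a similar pair whose mismatches
  recur at exactly the stride interval; the low `t` makes this rare, and
  the LCS filter cannot repair a miss that happens before it.
* Identity is measured against the representative only — members of one
  cluster can be pairwise less similar than $s$ to each other.
* The LCS bound loosens as reads grow (more room for gap-rich alignments
  with many matches), so pruning efficiency is best for short reads.
* `k` is capped at 12 by the direct-address table; protein alphabets and
  paired-end structure are out of scope.
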