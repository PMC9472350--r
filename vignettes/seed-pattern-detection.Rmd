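---
title: "Detecting LINE-1-like elements by seed-and-pattern matching"
author: "L1Detect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting LINE-1-like elements by seed-and-pattern matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(L1Detect)
library(GenomicRanges)
```

## The problem and the model

Full-length LINE-1 (L1) retrotransposons are ~6 kb elements with a 5'UTR,
two open reading frames (ORF1, ORF2) separated by a short inter-ORF linker,
a 3'UTR and a poly(A) tail.  Most genomic copies are truncated or decayed,
and seed-and-extend aligners (BLAST-like) drown full-length copies in
fragment hits.  This package implements the alternative *seed-and-pattern
match* strategy:

1. **Probe design.** From a multiple alignment of full-length, ORF-intact
   copies (the *query set*), find alignment columns whose modal base covers
   at least 95% of members, keep maximal runs of at least 50 such columns
   (conserved blocks, which in practice occur only inside the ORFs), and cut
   the blocks into candidate 50-mers.  Candidates are refined in three
   steps: drop candidates that also match outside their own ORF in any
   member; keep only candidates with the minimal number of exact hits on a
   background ("decoy") genome; and greedily select a non-overlapping subset
   left to right.  Each surviving probe \(p_i\) is stored 5'→3' with its
   average start offset and the average adjacent distances \(d_i\) between
   consecutive probe starts across the members.

2. **Seeding.** Each probe is mapped onto both strands of the target genome;
   a *seed* is a locus whose edit (Levenshtein) distance to the probe is at
   most \(\delta\).

3. **Pattern matching.** Seeds on one chromosome and strand form a *pattern
   match* when at least \(m\) of them occur in probe order and every
   consecutive pair satisfies \(|d_{ij} - g_{ij}| \le t\), where \(g_{ij}\)
   is the observed distance between seed starts and \(d_{ij}\) the expected
   distance (the telescoped sum \(d_i + \dots + d_{j-1}\), which handles
   skipped probes).  Chains are reported as elements in GFF3, with bounds
   extrapolated from the probes' average offsets.

The defaults \(m = 9\), \(t = 700\) bases and \(\delta = 20\) edits are the
F1-optimal operating point for 50-mer L1 probes; all three are exposed via
`detectionParams()`.

## Parameters that matter

| parameter | meaning | unit | default |
|---|---|---|---|
| `k` | probe length | bases | 50 |
| `minColumnSimilarity` | column conservation threshold | fraction | 0.95 |
| `minBlockLen` | minimal conserved run | columns | 50 |
| `m` | minimum seeds per pattern | count | 9 |
| `t` | spacing tolerance per link | bases | 700 |
| `delta` | maximum edit distance per seed | edits | 20 |
| `anchorLength` | exact-match anchor in the mapper | bases | 12 |

`m` trades recall for precision (more required seeds, fewer false patterns);
`t` absorbs indels between probe loci; `delta` absorbs divergence within
probe loci.  `parameterSweep()` recomputes precision/recall/F1 over a grid
and reports the F1 argmax, mapping once per distinct `delta`.

## The mapper and its sensitivity model

`mapProbe()` reports every window whose length is within `delta` of the
probe length, whose edit distance is at most `delta`, **and which shares an
exact 12-mer with the probe**.  The anchor condition is the sensitivity
model of index-based short-read mappers (the mapping stage this package
replaces used a 12-mer genome index): for 50-mer probes and
\(\delta \le 3\) it is implied by the distance bound — an alignment with at
most 3 edits must leave one of four ≥12-base probe fragments untouched — so
the mapper is provably exhaustive there, and the test suite verifies it
against a brute-force sliding-window oracle in exactly that regime.  At
\(\delta = 20\) (40% of a 50-mer) an unanchored exhaustive scan is neither
biologically meaningful nor computationally sane: on uniform random
sequence a 50-mer has on the order of thousands of sub-threshold alignment
end positions per megabase, which would bury the spacing pattern in chance
chains.  The anchor restores the practical regime: diverged but genuine
copies retain exact 12-mers, chance windows almost never do.

Implementation: exact anchors are located with a rolling 24-bit k-mer code;
candidate alignment end positions around anchors are prefiltered with
Myers' bit-vector semi-global scan, and surviving ends are verified with a
banded reverse DP that recovers every qualifying (start, end, distance)
window.  Overlapping windows are collapsed to one seed per locus: minimum
distance, ties to the leftmost start.  `N` bases never match.

## Chaining and reporting

Chains are paths in the DAG whose links are seed pairs passing the spacing
test.  A chain is *maximal* when no single seed can be prepended, appended
or inserted between two consecutive members without breaking a link;
maximal chains are exactly the source-to-sink paths over "tight" links
(links with no one-seed subdivision), which the package enumerates in
compiled code with an \(m\)-length pruning bound.  (The alternative
reading of maximality — not a subset of any other valid chain — differs in
contrived cases because the per-link test is not transitive;
non-extendability is the definition implemented and tested, including
against a brute-force oracle.)  On the minus strand probe order runs right
to left with the same expected gaps.

Overlapping chains (shared seeds, or overlapping inferred spans on the same
strand) are resolved greedily by more seeds, then smaller total deviation
\(\sum |d_{ij} - g_{ij}|\), then leftmost start, so each seed supports at
most one reported element.  Element bounds anchor the 5'-most seed at its
probe's average offset from the element start and extend the 3'-most seed
through the remaining layout plus the average tail; bounds are clamped to
the chromosome.  Coordinates are GRanges-style 1-based inclusive
everywhere inside the package; BED input (0-based half-open) is bridged at
I/O, and GFF3 output is written 1-based with fixed
`source=L1PD`, `type=mobile_genetic_element`, `Name=LINE1` fields, blank
score and phase.

## What the synthetic generator emulates

`makeElementModel()` builds a 6022-base consensus with the canonical human
L1 region lengths (5'UTR 908, ORF1 1017, inter-ORF 63, ORF2 3828, 3'UTR
206) and 16 conserved 60-column blocks (5 in ORF1, 11 in ORF2), mirroring
the published instance of five ORF1 plus eleven ORF2 probes.  One ORF2
inter-block gap is kept 480 bases wide so that a 396-base internal deletion
fits strictly between two consecutive probe loci (between probes 14 and
15), reproducing the documented edge case in which the element is detected
whenever a chain may skip the broken adjacency (\(m \le 14\)) and missed
when it may not (\(m > 14\)) at \(t = 50\).

`makeQuerySet()` derives members by substituting bases outside the blocks
at 8% per base and inside the blocks at 1% per base, the latter capped per
column at 5% of members so the planted blocks are guaranteed to pass the
conservation scan — reproducing the empirical situation in which conserved
blocks are islands in otherwise sub-threshold columns.  Members may lose
single bases outside blocks (0.002 per base) and end in a 10–30 base
poly(A) tail; alignments are returned gapped and column-consistent because
members never gain bases relative to the consensus (insertions are not
simulated; this is the one simplification relative to real alignments, and
it does not affect what the detector sees, which is the ungapped members).

`plantElements()` places mutated copies at non-overlapping positions on
random uniform ACGT background, with Bernoulli(0.5) strands and integrity
classes `intact`, `truncated` (5' prefix removed), `deleted` (the 396-base
internal deletion) and `decayed` (60% substitution, which pushes probe loci
beyond \(\delta = 20\)).  `perturbGenome()` deletes whole planted spans
and/or inserts fresh intact copies, updating truth coordinates — the basis
of the linear-response experiment in which the match count tracks
\(50 + n\) exactly for \(n \in \{-20, \dots, +20\}\).

What passing these tests shows — and does not show.  The generator
reproduces the *structural* features the method exploits (conserved blocks
in two ORFs, stable inter-probe spacing, truncation/deletion/decay classes,
both strands) but not repeat-rich background, nested or overlapping
insertions, target-site duplications, GC bias, or a realistic phylogeny of
element subfamilies.  Perfect precision/recall on intact-only synthetic
genomes is a construction guarantee, not a claim about real genomes, where
degraded fragments dominate and precision is set by how many of them still
chain.

## Numerical and design choices

* Gap columns count against conservation (the modal base is always a real
  base, and its fraction is over all members): a probe must exist as a
  contiguous k-mer in most members.
* Candidate 50-mers are enumerated at every offset within a block; the
  non-overlap selection is greedy left-to-right (deterministic, preserves
  5'→3' coverage); Step-2 ties (equal minimal decoy hits) all survive.
* Offsets and distances are arithmetic means over members carrying the
  probe, rounded to the nearest base; probes found in under half the
  members are dropped with a warning.
* The link test uses the telescoped expected gap with the same per-link
  threshold `t` when probes are missing (no cumulative scaling) — the
  simplest consistent generalization of the published adjacent-pair
  inequality.  Gaps are measured start-to-start, matching how offsets are
  averaged.
* Chain enumeration carries a 100,000-chains-per-strand safety cap
  (warning if hit); it is unreachable on the workloads in this package.
* Evaluation matches predictions to truth one-to-one by descending overlap,
  requiring the same strand and any positive overlap by default; a
  reciprocal-overlap option (e.g. 0.5) is available for stricter scoring.
  Zero denominators yield precision = recall = F1 = 0 so sweeps stay total.
* CNVPG \(= (SPC - RPC)/RPC \times 100\) is exact internally and rounded to
  5 decimals only for presentation.

## Problem sizes used by the tests

The packaged experiments run on a single CPU in a few minutes: a 40-member
query set; detection genomes of 25–50 planted copies in 150–300 kb of
background; the perturbation experiment at 50 copies with
\(n \in \{-20,\dots,20\}\); mapper-oracle instances of 1.2–20 kb at
\(\delta \le 3\); and 200 random ≤12-seed chaining instances.  These sizes
exercise every code path at full fidelity; nothing in the method is
specific to them, and the compiled mapper scales linearly in genome length.

## A worked example

```{r example}
model <- makeElementModel(seed = 101)
query <- makeQuerySet(model, n = 40, seed = 202)
decoy <- plantElements(model, 0, backgroundLength = 20000, seed = 303)$genome
probes <- designProbes(query, decoy)
probes

sim <- plantElements(model, nCopies = 10, backgroundLength = 1e5, seed = 404)
hits <- detectElements(sim$genome, probes)
hits
precisionRecallF1(matchPredictions(hits, sim$truth))
```

## Known limitations

* Sensitivity beyond \(\delta = 3\) is anchor-limited by design; a copy
  whose every probe locus has diverged past the point of retaining any
  exact 12-mer will not seed.
* Poly(A) tails and UTRs are outside probe coverage; element bounds at the
  UTR ends are extrapolated, not observed, so their accuracy is bounded by
  the layout averages.
* The evaluation criterion (positive same-strand overlap, one-to-one) is a
  choice; published precision/recall values on real genomes depend on the
  original study's unstated criterion and are not reproduction targets.
* The probe count is not fixed at 16; it is a property of the query class.
  The packaged synthetic class yields 16 by construction.
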