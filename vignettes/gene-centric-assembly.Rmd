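---
title: "Gene-centric assembly from protein alignments: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric assembly from protein alignments: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcassembler)
```

## The problem

In a metagenome, one is often interested in a single family of orthologous
genes — say, a KEGG orthology group — rather than in whole-genome assemblies.
Reads belonging to such a family are recruited by translated (BLASTX-style)
alignment against the family's reference proteins. `gcassembler` assembles
exactly those reads, per family, into contigs.

The key idea is that the protein alignments themselves tell us which reads
overlap and how. If two reads align to the same reference protein and their
alignments share reference positions, the shared positions imply a placement
of one read against the other at nucleotide resolution. We therefore never
compute read-vs-read alignments: overlaps are *induced* by the protein
alignments and then verified on the DNA.

## The model

**Aligned cores.** Each read `r` is reduced to its *aligned core* `c(r)`:
the segment covered by its highest-scoring local protein alignment, oriented
to the coding strand (reverse-complemented when the frame is negative). The
core is always a whole number of codons, and translating it in frame +1
reproduces the alignment's query residues. Working with cores instead of
full reads acts as alignment-driven quality trimming: read ends that do not
align as protein are never used.

**The overlap graph G.** Nodes are cores. For each reference protein, every
ordered pair of cores projecting onto it is examined: the smallest shared
reference position (among columns ungapped in both query and subject) fixes
the placement of core *b* inside core *a*. The pair contributes a directed
edge *a → b* when

1. the placement is a suffix-prefix layout (*b* starts inside *a* and
   extends at least to *a*'s end — containments yield no edge),
2. all shared positions agree on the same placement (an indel between the
   reads rejects the pair, keeping induced alignments gap-free),
3. the overlapping DNA is *exactly* identical (by default N matches
   nothing, not even N), and
4. the overlap length reaches `minOverlapReads` (default 20 nt, inclusive).

The edge weight ω(e) is the induced DNA overlap length in nucleotides.
Parallel candidates from different references collapse to the maximum
weight. With `k` references and `n` cores the construction examines at most
O(k·n²) pairs, and at most one edge per ordered pair survives.

**Layout.** Directed cycles (rare within a single gene family, but possible
through repeats) are removed first: a depth-first search finds a cycle, its
minimum-weight edge is deleted (ties: lexicographically smallest node pair),
and the search restarts; termination is immediate since every step deletes
an edge. On the resulting DAG, the maximum-weight path — the path maximizing
the total number of overlapping nucleotides — is found by relaxing vertices
in topological order (linear time). The layout loop repeats: take the
heaviest path, build its contig, report it if it passes the filters, remove
the path's nodes, stop when the graph is empty. Filtered-out candidates are
removed from the graph all the same, so no read is used twice and extracted
path weights are non-increasing.

**Consensus.** Because overlaps are perfect, consensus is concatenation:
start with the first core and append each successive core minus its
overlapped prefix. Every member core is an exact substring of its contig,
and the contig length equals the summed core lengths minus the summed edge
weights. Average coverage is the summed member length over the contig
length.

**The contig graph H.** A second graph over the reported contigs handles
the redundancy that sequencing errors create. A contig contained in a
strictly longer one at ≥ `minPercentIdentityContigs` (default 98%) under
some ungapped placement is discarded; equal-length near-duplicates keep the
lexicographically smaller id. Remaining contigs are connected by a directed
edge when a suffix-prefix ungapped overlap of ≥ `minOverlapContigs`
(default 20 nt) reaches the identity threshold, and the same
cycle-break/heaviest-path machinery merges them. At a mismatching overlap
column the character from the contig with more reads covering that column
wins (ties keep the earlier contig in the path).

## Parameters

| parameter | unit | default | meaning |
|---|---|---|---|
| `minOverlapReads` | nt | 20 | minimum induced read-read overlap |
| `minReads` | count | 2 | minimum reads per reported contig |
| `minLength` | nt | 200 | minimum contig length |
| `minAvCoverage` | ratio | 0 | minimum average coverage (0 = inactive) |
| `minOverlapContigs` | nt | 20 | minimum contig-contig overlap for merging |
| `minPercentIdentityContigs` | % | 98 | identity for containment and merging |

All thresholds are inclusive lower bounds. `minAvCoverage` defaults to 0
because coverage filtering is rarely useful at gene scale and single-read
contigs are already removed by `minReads = 2`. Raising
`minPercentIdentityContigs` to 99 makes containment removal stricter and can
leave a few more near-duplicate contigs in the output; it is the same
parameter, not a separate mode.

## Numerical and design choices

* **Score for "highest-scoring".** The bit score column of the alignment
  table; ties prefer the longer read interval, then the smaller reference
  id, making core selection deterministic.
* **Foreign alignments are clipped to the core.** An alignment other than
  the defining one may extend outside the core; only the codons falling
  inside the core contribute to projections, keeping node sequences and
  edge evidence consistent. Alignments on the opposite strand of the core
  are ignored entirely.
* **Threshold semantics.** "Exceeds the threshold" is implemented as `>=`
  uniformly, so the printed default (20) is itself admissible.
* **Containment/overlap detection for H** is exhaustive ungapped sliding
  placement with a mismatch budget of ⌊(1 − identity)·L⌋. Gene-scale contig
  sets (tens to hundreds of contigs of roughly gene length) make the
  quadratic scan affordable, and no gap model is defined for this stage;
  gapped contig alignment is out of scope.
* **Tie-breaks everywhere** (equal-weight predecessors and terminals in the
  path search, equal-weight cycle edges, equal-score alignments, parallel
  edges from different references) resolve to the lexicographically smaller
  id, so identical inputs give byte-identical outputs regardless of input
  order.
* **Degenerate inputs.** An empty alignment set is a warning plus zero
  contigs, not an error; an empty graph yields an empty contig list; a
  single isolated core forms a singleton candidate that the default
  `minReads = 2` discards.

## What the simulator emulates — and what it does not

`simulation_spec()` / `write_fixture()` generate: a random stop-free coding
gene (999 nt by default), a reference family (the exact translation plus
references diverged by i.i.d. amino-acid substitutions, 5% by default),
reads of 101 nt tiled every 50 nt with the last window clamped to the gene
end (19 reads at the defaults), optional strand flips and per-nucleotide
substitution errors, and the alignment records a translated search would
produce. The simulated aligner knows each read's true origin: coordinates
are exact, alignments are ungapped, and read intervals are trimmed to whole
codons of the true frame, mirroring how local protein alignment ignores
partial codons. Read ids encode the origin (`prefix|start|strand`) so tests
can check assemblies against ground truth.

The simulator does **not** model alignment noise (wrong frames, spurious
hits, chimeras), indel sequencing errors (an optional rejection-path test
uses hand-built records instead), quality values, GC bias, or paired ends.
Passing tests on these fixtures therefore demonstrate the correctness of
the graph construction, layout and merging logic under the stated
assumptions — not the recall of a real translated aligner on real
metagenomes.

Problem sizes used by the test suite — a 999-nt gene with 19 reads and 3
references for end-to-end runs, 200 random DAGs of ≤ 12 nodes checked
against exhaustive path enumeration, 100 random graphs with planted cycles,
20 fixtures for the filter-monotonicity sweep — are small enough to run in
seconds while covering every code path; the assembler itself handles the
tens of thousands of reads a well-covered gene family attracts.

## Known limitations

* One gene family per invocation; batch assembly is a shell loop over
  families.
* Overlaps are strictly gap-free with perfect identity; a single sequencing
  error inside every candidate overlap isolates a read (it then fails
  `minReads`). This is by design — specificity over sensitivity — and is
  what keeps consensus trivial.
* Containment detection is ungapped, so an indel variant of a contig is not
  recognized as contained.
* The maximum-weight path is a greedy per-iteration optimum; no global
  path cover objective is optimized.
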