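---
title: "Assembly-based inference of B-cell receptor repertoires: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly-based inference of B-cell receptor repertoires: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Expressed B-cell receptor (BCR) transcripts are present in any bulk RNA-seq
library that contains B cells, but standard aligners cannot reconstruct
them: each receptor is a private V(D)J rearrangement with non-templated
junctional nucleotides and somatic hypermutation (SHM), so the molecule of
interest does not exist in the reference genome. `igasm` recovers heavy- or
light-chain sequences from short paired-end mRNA-seq alignments by targeted
de Bruijn graph assembly, then derives clonotypes, abundances and
repertoire diversity from the assembled contigs.

The pipeline has four stages: candidate read extraction, quality-aware
graph construction, scored traversal from germline-V-homologous sources,
and read-level contig confirmation; postprocessing assigns isotypes and
V/J genes, quantifies abundance by expectation–maximization (EM) and
clusters clonotypes.

## Read extraction

A read enters assembly when it (1) maps inside a configured immunoglobulin
locus interval, (2) is mapped and shares a 15-mer (either strand) with the
functional germline V/D/J segments of the chain, or (3) is unmapped; in
every case the mate is extracted too, so pairing is preserved. The 15-mer
index contains both strands because RNA-seq protocols are typically
unstranded. Secondary and supplementary records are ignored (a physical
read must be counted once); duplicate-marked reads are retained because
assembly depth depends on them.

## Graph construction and pruning

Every extracted read is inserted into a de Bruijn graph in both
orientations. A vertex is a k-mer carrying its observation count, the
number of distinct supporting reads, and the per-position sum of Phred
base qualities; an edge is an observed (k+1)-mer with its frequency.
Pruning removes vertices below a minimum count (default 2), vertices whose
summed quality at any k-mer position falls below a threshold (default 60),
and vertices supported by a single distinct read. Maximal forced chains
are condensed into single nodes; a chain cycle is broken at its
lexicographically smallest k-mer (the closing edge is dropped) so output
is deterministic.

The default k is 35 for 2×50 bp reads (sensitive mode: 25). The choice is
driven by SHM: two clones using the same germline V differ at scattered
point mutations, and their graph paths re-join wherever they share k−1
identical bases. Small k therefore braids same-V clones into
exponentially many mosaic paths; k = 35 requires a 34-base identical run
to re-join, which keeps the braid — and the candidate set the confirmation
stage must resolve — small, while 50-base reads still provide ~16
overlapping k-mers of evidence per position.

## Traversal

Condensed nodes with no incoming edge are candidate sources. Each is
scored against the germline V segments with an exact 12-mer hash seed
followed by local (Smith–Waterman) alignment (match +1, mismatch −1, gap
−4); sources reaching score 23 seed depth-first traversal. At a branch,
each outgoing edge has ratio `frequency / total outgoing frequency` (one
for a single out-edge) and the path score is the running product of the
traversed ratios. A path ends at a sink or at the maximum contig length
(default 360 nt, flagged truncated), is emitted if at least 250 nt, and is
abandoned when its score drops below the configured floor.

The path-score floor is deliberately conservative (standard 1e-15): in a
repertoire where a weak clone shares its V segment with clones hundreds of
times deeper, the true path takes minor-arm edges with ratios of a few
percent, and any permissive floor silently discards exactly the weak
clones. Specificity is instead enforced downstream by read-level
confirmation, which has direct evidence; the score floor remains as a
guard against pathological graphs, and the per-source emission budget
(default 10000) bounds worst-case work.

## Contig confirmation

A candidate contig must first show a 16-base V anchor and J anchor at no
more than 4 mismatches. Anchors are taken 8 nt in from the V 3' end and
J 5' start: junctional exonuclease trimming erodes the termini themselves,
and a terminal anchor accrues ~0.75 mismatches per trimmed base against
the rearranged sequence. The reading frame is fixed by the V anchor
position plus the germline V frame offset; the CDR3 call requires an
in-frame conserved cysteine codon just after the V anchor and tryptophan
(IGH) or phenylalanine (IGK/IGL) inside the J anchor region, an
amino-acid span inside the configured window (IGH 5–38), and no stop
codon; the innermost Cys/Trp pair wins.

Confirmation then maps the extracted reads back by perfect matching: a
pair is mapped iff both mates are exact substrings in opposite
orientations, forward mate upstream, insert within [50, 1000]. Each
candidate is trimmed to its read-confirmed span. The head is cut to the
first position with pair depth ≥ 2 — the first ~k bases of any path are
spelled by k-mers whose supporting reads overhang the contig start and
can never map back, so they carry no pair-level evidence. The tail is cut
to the farthest reach of junction-anchored pairs (fragments that overlap
the V anchor), and additionally capped at a fixed 80 nt past the J anchor.
The cap keeps all accepted contigs covering a comparable stretch of the
shared constant region: without it, the contig reaching deepest into the
constant region absorbs every clone's constant-resident fragments during
quantification, which distorts abundance estimates. A fragment can only be
misassigned between two contigs when it fits entirely inside a region one
covers and the other does not, so bounding differential extents below the
minimum fragment span removes the effect.

Accepted contigs must retain ≥ 10 mapped pairs, depth ≥ 2 at every
confirmed base, ≥ 5 distinct mate start positions, and mate start
positions tiling the span with no gap above 25 nt (with a sentinel at the
last startable offset, so an unsupported tail registers as a gap).

### Mosaic suppression

Exhaustive traversal of SHM braids necessarily emits mosaic paths that
switch between same-V clones at shared runs; every read window of such a
chimera is genuine, so window-level checks cannot reject it. Two
observations do: a mosaic has a structural hole in mapped start positions
around its crossover (no physical read spans it), and its mapped pairs
are a subset of its parents' pairs, so it never carries support unique to
itself while its parents are present. After substring/reverse-complement
containment dedup, candidates are therefore peeled iteratively: while any
candidate holds fewer than 3 pairs unique to it (counted away from the
span margins, so trim bookkeeping cannot fabricate uniqueness), the one
carrying the least expected fragment mass under a shared EM allocation is
removed and uniqueness is recomputed. Parents attract the mass of their
own unique windows and junction reads; mosaics live off shared windows
split many ways, so they are peeled first, and once a family's mosaics
are gone its true clones regain their unique support and the loop stops.
The uniqueness floor sits at 3 because a sequencing error recurring in two
distinct reads survives the graph's distinct-read pruning and yields a
one-substitution variant carrying exactly two "unique" pairs.

## Postprocessing

The trailing 48 bases of each contig are matched ungapped against every
window of the supplied constant-region references; the best match at ≤ 4
mismatches assigns the isotype, ties across isotype classes yield
`unknown`. V and J genes are called by the same local alignment as source
screening, upstream and downstream of the CDR3; V identity
(matches/aligned columns) proxies SHM load. Abundance is quantified by a
length-normalized multinomial EM over mapped pairs — unique pairs
contribute wholly, multi-mapping pairs fractionally — conserving the
mapped-pair total. Contigs identical in CDR3 amino acids, V gene, J gene
and isotype form one clonotype whose abundance is the member sum.
Repertoire summaries report richness, total abundance, Pielou evenness
(Shannon entropy over clonotype proportions divided by log richness;
natural log, single-clonotype convention 0) and the abundance/evenness
stratification (abundance cut 1000, evenness cut 0.8, boundaries counted
low).

## The simulator

The generator emulates the conditions the assembler targets: a synthetic
germline (default 20 V / 6 D / 5 J / 3 C segments at uniform base
composition) in which every V carries an in-frame conserved cysteine 9 nt
from its 3' end and every J a tryptophan 12 nt from its 5' start, so
recombinants present detectable CDR3s; V(D)J recombination with 0–5 nt
exonuclease trims and 0–10 nt junctional insertions (the second insertion
stretched by 0–2 nt to keep the junction in frame, mirroring selection
for productive rearrangements); SHM at 2% per V-region base sparing the
conserved cysteine; 2×50 bp pairs from fragments of 180 ± 30 nt placed
uniformly at the requested mean depth; substitution errors at 0.2% per
base with matching quality strings (35, errors at 12); and mapped decoy
background pairs so extraction is exercised. Every operation is
deterministic under the seed. Synthetic V segments default to 220–250 nt
— shorter than real germline V genes — so that a 360 nt contig spans the
V(D)J junction and enough constant sequence for isotype assignment at
this desk scale.

What the simulator does not model: splicing and transcriptome background
beyond random decoys, empirical (position- and context-dependent) error
profiles, indel errors, allele-level germline variation, and clone
abundance distributions beyond the configured per-clone depths. Passing
simulation benchmarks therefore demonstrates the assembly and
quantification logic under controlled junctional and SHM diversity, not
performance on real libraries.

Evaluation counts a simulated clonotype as detected when an accepted
contig matches it ungapped, either strand, within a configured mismatch
allowance (reported at 0 and at 2 mismatches); a contig matching no
clonotype is a false positive. Abundance agreement is the squared Pearson
correlation between per-clonotype EM fragment estimates — as densities
per placeable fragment start, so contigs of unequal confirmed span stay
comparable — and the simulated depths, over detected clonotypes.

## Benchmarks and problem sizes

The packaged benchmarks (also recomputed by `scripts/acceptance.R`) use
30 clonotypes at uniform 50× depth across five seeds for
sensitivity/specificity, and 50 clonotypes at depths drawn from
{25, 50, 100, 250, 500} across three seeds for abundance recovery. At
these sizes a full run — simulation, assembly, confirmation and
quantification — takes on the order of half a minute to two minutes per
replicate. Deeper repertoires scale roughly linearly in read count.

## Known limitations

* Same-V clones whose weakly covered 5' head regions fuse through a
  shared corridor can yield a contig that joins one clone's head to
  another's body; when the borrowed head belongs to sequence absent from
  every other accepted contig, the fusion is supported by real, otherwise
  unexplained reads and cannot be rejected at the read level. This is
  rare at uniform depth and confined to the lowest-coverage clones in
  highly skewed repertoires.
* Perfect-match read mapping ignores reads carrying any sequencing error;
  depth-dependent thresholds assume the ~80% pair survival this implies
  at 0.2% error.
* Heavy/light chain pairing is out of scope, as are split or chimeric
  reference genomes for extraction (locus intervals are user
  configuration).
* Isotype assignment needs the contig to retain `tail_len` (48) constant
  bases after the junction; contigs whose confirmed span ends earlier are
  reported `unknown`.
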