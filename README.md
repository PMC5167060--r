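# igasm

Targeted de Bruijn graph assembly of B-cell receptor (BCR) repertoires
from short-read RNA-seq.

## What it does and for whom

Bulk mRNA-seq of any tissue containing B cells carries the expressed
immunoglobulin heavy- (IGH) and light-chain (IGK/IGL) transcripts, but
each receptor is a private V(D)J rearrangement — germline V, (D) and J
segments joined with exonuclease-trimmed ends and non-templated junction
nucleotides, further diversified by somatic hypermutation (SHM) — so it
aligns to no reference. `igasm` reconstructs these sequences directly from
a standard aligned SAM/BAM, for immunologists and tumor-immunology groups
who want repertoire readouts (clonotypes, V/J usage, isotypes, CDR3s,
clonal diversity) from RNA-seq that was not generated for repertoire
profiling.

The method:

1. **Extract** candidate reads: reads mapping to configured IG loci, mapped
   reads sharing a 15-mer with the chain's functional germline V/D/J
   segments (either strand), and all unmapped reads — always together with
   their mates.
2. **Assemble** a quality-aware de Bruijn graph (vertices are k-mers with
   observation counts, distinct-read counts and per-position base-quality
   sums; default k = 35), prune weak vertices, condense linear chains.
3. **Traverse** from zero-in-degree nodes that pass a germline-V homology
   screen (12-mer hash seed + Smith–Waterman). A path's score is the
   product of edge ratios (edge frequency over total outgoing frequency);
   traversal stops at sinks, at the 360 nt contig cap, or below the score
   floor.
4. **Confirm** contigs: 16-base germline V and J anchors at ≤ 4 mismatches,
   an in-frame CDR3 delimited by the conserved Cys and Trp/Phe, perfect
   paired-read re-mapping, trimming to the read-confirmed span, and
   mosaic/chimera suppression via coverage contiguity and cross-contig
   unique pair support.
5. **Postprocess**: isotype from the trailing 48 bases against
   constant-region references, V/J gene and V-identity (SHM proxy) by local
   alignment, abundance by an EM over multi-mapping read pairs, clonotype
   clustering on identical (CDR3 amino acids, V gene, J gene, isotype),
   and repertoire summaries — richness, total abundance, Pielou evenness
   `E = −Σ pᵢ ln pᵢ / ln S`, and abundance/evenness stratification.

A seed-deterministic simulator (`sim_config()`, `simulate_germline()`,
`recombine()`, `generate_reads()`, `write_sim()`, `evaluate_assembly()`)
generates synthetic germlines, V(D)J-recombined and hypermutated
clonotypes, and 2×50 bp read sets with errors and decoy background, for
end-to-end validation.

## Worked example

Simulate a small IgH repertoire and run the pipeline end to end:

```r
library(igasm)
cfg <- sim_config(seed = 7, n_clonotypes = 8, depth = 60)
db <- simulate_germline(cfg)
truth <- recombine(cfg, db)
sim <- generate_reads(truth, cfg)
files <- write_sim(sim, db, "example_sim")
pc <- pipeline_config(alignments = files[["sam"]],
                      germline_fasta = files[["germline_fasta"]],
                      germline_meta = files[["germline_meta"]],
                      out_dir = "example_out")
res <- run_pipeline(pc)
res$clonotypes[, c("clonotype_id", "cdr3_aa", "v_gene", "j_gene",
                   "isotype", "abundance")]
#>    clonotype_id       cdr3_aa      v_gene   j_gene isotype abundance
#> 1:    clone0001 CLLELLVNCLKDW  IGHV3-1*01 IGHJ2*01    IGHM       140
#> 2:    clone0002  CSFNWSNPVKDW IGHV13-1*01 IGHJ2*01    IGHM       136
#> 3:    clone0003   CLLLESRVFAW IGHV17-1*01 IGHJ5*01    IGHM       125
#> 4:    clone0004    CLHAHAAQHW  IGHV2-1*01 IGHJ3*01    IGHG       125
#> 5:    clone0005  CSGFGNFPVKDW IGHV20-1*01 IGHJ2*01    IGHA       121
#> 6:    clone0006  CGYRCGSRCFRW  IGHV4-1*01 IGHJ4*01    IGHA       113
#> 7:    clone0007   CDFGQFRCFRW  IGHV8-1*01 IGHJ4*01    IGHG       113
#> 8:    clone0008     CRFLLTQHW IGHV19-1*01 IGHJ3*01    IGHG       111
```

Each row is one clonotype: its CDR3 amino-acid sequence (conserved C ... W
flanks included), the assigned germline V and J genes, the isotype read
off the assembled constant-region tail, and the EM-estimated fragment
count. The summary and the truth comparison:

```r
res$summary[c("richness", "total_abundance", "evenness", "group")]
#> richness 8 | total abundance 984 | evenness 0.998 | group low_abundance
evaluate_assembly(res$contigs, truth)[c("sensitivity", "false_positives")]
#> sensitivity 1.00 | false positives 0
```

All eight simulated clonotypes are recovered exactly (every accepted
contig matches a simulated sequence with zero mismatches) and the per-base
depths of 60× yield ~120–140 mapped fragments per clone. The eight near
equal abundances give an evenness close to 1 (a perfectly even
repertoire); a sample dominated by one expanded clone would score far
lower.

With an output directory set, the run also writes `contigs.fasta`, a
`contigs.sam` of perfectly mapped pairs (one `@SQ` per contig),
`clonotypes.tsv`, `summary.tsv` and a YAML run log with per-stage counts.
A command-line wrapper with `run` / `extract` / `simulate` / `evaluate`
subcommands is in `inst/scripts/igasm.R`.

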