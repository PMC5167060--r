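# Independent oracles used to verify the implementation. These deliberately
# avoid the package's own code paths (and Biostrings, where the package
# relies on it) so that implementation and check stay separate.

# brute-force k-mer enumeration over a set of sequences (forward only)
oracle_kmers <- function(seqs, k) {
  unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
}

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, NULL)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# plain Smith-Waterman with linear gap penalty, O(nm) dynamic programming
oracle_sw <- function(a, b, match = 1, mismatch = -1, gap = -4) {
  av <- strsplit(a, NULL)[[1]]
  bv <- strsplit(b, NULL)[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (av[i] == bv[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] + gap,
                             H[i + 1, j] + gap)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# Hamming distance scan of a pattern along a subject
oracle_hamming_scan <- function(subject, pattern) {
  sv <- strsplit(subject, NULL)[[1]]
  pv <- strsplit(pattern, NULL)[[1]]
  n <- length(sv); m <- length(pv)
  if (n < m) return(integer(0))
  vapply(1:(n - m + 1L), function(p) sum(sv[p:(p + m - 1L)] != pv),
         integer(1))
}

# independent codon table (distinct source from Biostrings::GENETIC_CODE)
oracle_translate <- function(seq) {
  tab <- c(
    TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
    ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
    TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
    ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
    TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
    AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
    TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
    AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")
  n <- nchar(seq)
  codons <- substring(seq, seq(1, n, 3), seq(3, n, 3))
  paste(tab[codons], collapse = "")
}

# exhaustive path enumeration with the traversal stopping rules
oracle_enumerate_paths <- function(nodes, edges, sources, k,
                                   min_path_score, max_contig_len,
                                   min_contig_len) {
  seq_of <- setNames(nodes$seq, nodes$id)
  out <- list()
  recurse <- function(node, seqs, score) {
    if (nchar(seqs) >= max_contig_len) {
      out[[length(out) + 1L]] <<- list(seq = substr(seqs, 1, max_contig_len),
                                       score = score)
      return(invisible())
    }
    ch <- edges[edges$from == node, , drop = FALSE]
    if (nrow(ch) == 0L) {
      if (nchar(seqs) >= min_contig_len)
        out[[length(out) + 1L]] <<- list(seq = seqs, score = score)
      return(invisible())
    }
    total <- sum(ch$freq)
    for (i in seq_len(nrow(ch))) {
      sc <- score * ch$freq[i] / total
      if (sc < min_path_score) next
      recurse(ch$to[i], paste0(seqs, substring(seq_of[[ch$to[i]]], k)), sc)
    }
  }
  for (s in sources) recurse(s, seq_of[[s]], 1.0)
  out
}

# likelihood grid search for the 2-contig EM instance (equal lengths):
# n_a unique to A, n_b unique to B, n_s shared
oracle_em_2contig <- function(n_a, n_b, n_s, grid = seq(0.0005, 0.9995, 5e-4)) {
  ll <- n_a * log(grid) + n_b * log(1 - grid) + n_s * log(1)
  th <- grid[which.max(ll)]
  n <- n_a + n_b + n_s
  # expected counts under the ML mixture
  c(a = n_a + n_s * th, b = n_b + n_s * (1 - th))
}

# tiny deterministic germline fixture built in code
make_tiny_germline <- function(dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  v1 <- paste0(strrep("ACGGT", 20), "TGT", "AACCGG")         # 109 nt, Cys at 100
  v2 <- paste0(strrep("GATTC", 20), "TGT", "CCAATT")
  j1 <- paste0("ACGTACGTACGT", "TGG", strrep("CATG", 9))     # 51 nt, Trp at 12
  d1 <- "GGGTTTCCCAAAGG"
  c1 <- strrep("TTGACA", 12)                                 # 72 nt
  fa <- file.path(dir, "germ.fa")
  writeLines(c(">V1", v1, ">V2", v2, ">D1", d1, ">J1", j1, ">C1", c1), fa)
  meta <- file.path(dir, "germ.tsv")
  writeLines(c("id\tchain\tclass\tfunctional\tframe_offset",
               "V1\tIGH\tV\tTRUE\t1",
               "V2\tIGH\tV\tTRUE\t0",
               "D1\tIGH\tD\tTRUE\tNA",
               "J1\tIGH\tJ\tTRUE\tNA",
               "C1\tIGH\tC\tTRUE\tNA"), meta)
  list(fasta = fa, meta = meta, v1 = v1, v2 = v2, d1 = d1, j1 = j1, c1 = c1)
}

# write a small SAM file from a record table (list of character vectors)
write_test_sam <- function(records, path, sq = c(chr1 = 1000L)) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", names(sq), "\tLN:", sq),
           "@PG\tID:test\tPN:test")
  writeLines(c(hdr, vapply(records, paste, character(1), collapse = "\t")),
             path)
  path
}

sam_rec <- function(qname, flag, rname = "*", pos = 0L, seq, qual = NULL) {
  if (is.null(qual)) qual <- strrep("D", nchar(seq))
  c(qname, flag, rname, pos, if (rname == "*") 0L else 60L,
    if (rname == "*") "*" else paste0(nchar(seq), "M"),
    "*", 0L, 0L, seq, qual)
}
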