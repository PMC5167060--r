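#' Read an alignment file into a read table
#'
#' Loads primary records from a SAM or BAM file (SAM is converted via
#' Rsamtools). Secondary and supplementary alignments are dropped: only
#' primary records represent a physical read. Duplicate-marked reads are
#' retained because assembly depth depends on them.
#'
#' @param path SAM or BAM file.
#' @return a `read_set` data.table with columns `name`, `read_index` (1/2),
#'   `seq`, `qual` (Phred+33 string, alignment orientation), `mapped`,
#'   `rname`, `pos`, `reverse`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- tempfile(fileext = ".bam")
    Rsamtools::asBam(path, sub("\\.bam$", "", bam), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "seq", "qual"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- rec$flag
  keep <- bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L
  rs <- data.table(
    name = rec$qname[keep],
    read_index = ifelse(bitwAnd(flag[keep], 128L) != 0L, 2L, 1L),
    seq = as.character(rec$seq)[keep],
    qual = as.character(rec$qual)[keep],
    mapped = bitwAnd(flag[keep], 4L) == 0L,
    rname = as.character(rec$rname)[keep],
    pos = rec$pos[keep],
    reverse = bitwAnd(flag[keep], 16L) != 0L
  )
  if (any(rs$qual == "" | rs$qual == "*"))
    stop("alignment stream without base quality strings")
  dup <- duplicated(rs[, .(name, read_index)])
  if (any(dup)) {
    warning(sum(dup), " duplicate (name, read_index) record(s); keeping first")
    rs <- rs[!dup]
  }
  class(rs) <- c("read_set", class(rs))
  rs
}

#' Load locus intervals from a BED file
#'
#' @param bed_path BED file (0-based half-open) of functional IG loci.
#' @param chain chain label attached to the spec.
#' @return a `locus_spec`: GRanges plus chain.
#' @export
load_loci <- function(bed_path, chain = "IGH") {
  if (!file.exists(bed_path)) stop("locus BED not found: ", bed_path)
  bed <- read.table(bed_path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  stopifnot(ncol(bed) >= 3L, all(bed[[2]] < bed[[3]]))
  gr <- GenomicRanges::GRanges(
    seqnames = bed[[1]],
    ranges = IRanges::IRanges(start = bed[[2]] + 1L, end = bed[[3]])
  )
  structure(list(intervals = gr, chain = chain), class = "locus_spec")
}

#' Extract candidate BCR reads
#'
#' A read is selected iff it (1) maps within a configured IG locus interval,
#' (2) is mapped and shares at least one k-mer (either strand) with the
#' germline V/D/J index, (3) is unmapped, or (4) its mate satisfies 1-3
#' (mate rescue). Each physical read appears at most once; pairing is
#' preserved.
#'
#' @param reads a `read_set` from [read_alignments()].
#' @param loci a `locus_spec` or NULL (criterion 1 skipped).
#' @param kmer_index character vector from [build_kmer_index()].
#' @param k k-mer length of the index (default 15).
#' @return a `read_set` restricted to candidates, with a `reason` column
#'   (`locus`, `kmer`, `unmapped`, `mate`) and an attribute
#'   `extraction_report` of per-criterion counts.
#' @export
extract_candidate_reads <- function(reads, loci = NULL, kmer_index = character(0),
                                    k = 15L) {
  rs <- as.data.table(reads)
  n <- nrow(rs)
  by_locus <- rep(FALSE, n)
  if (!is.null(loci) && n > 0L) {
    m <- rs$mapped & !is.na(rs$pos) & !is.na(rs$rname)
    if (any(m)) {
      gr <- GenomicRanges::GRanges(
        seqnames = rs$rname[m],
        ranges = IRanges::IRanges(start = rs$pos[m],
                                  width = nchar(rs$seq[m]))
      )
      hits <- GenomicRanges::countOverlaps(gr, loci$intervals,
                                           ignore.strand = TRUE) > 0L
      by_locus[which(m)[hits]] <- TRUE
    }
  }
  by_unmapped <- !rs$mapped
  by_kmer <- rep(FALSE, n)
  cand <- which(rs$mapped & !by_locus)
  if (length(cand) > 0L && length(kmer_index) > 0L) {
    by_kmer[cand] <- has_index_kmer(rs$seq[cand], kmer_index, k)
  }
  selected <- by_locus | by_unmapped | by_kmer
  # mate rescue: a read is always extracted along with its paired read
  sel_names <- unique(rs$name[selected])
  by_mate <- !selected & rs$name %chin% sel_names
  out <- rs[selected | by_mate]
  reason <- character(nrow(out))
  idx <- selected | by_mate
  reason[by_locus[idx]] <- "locus"
  reason[!by_locus[idx] & by_kmer[idx]] <- "kmer"
  reason[!by_locus[idx] & !by_kmer[idx] & by_unmapped[idx]] <- "unmapped"
  reason[reason == ""] <- "mate"
  out[, reason := reason]
  # orphan warning: selected read whose mate is absent from the file
  cnt <- out[, .N, by = name]
  if (any(cnt$N == 1L))
    warning(sum(cnt$N == 1L), " extracted read(s) without a mate in the input")
  report <- c(total_input = n, locus = sum(by_locus), kmer = sum(by_kmer),
              unmapped = sum(by_unmapped), mate_rescue = sum(by_mate),
              extracted = nrow(out))
  data.table::setattr(out, "extraction_report", report)
  class(out) <- c("read_set", class(out))
  out
}

# TRUE for each sequence that contains >=1 index k-mer on either strand
has_index_kmer <- function(seqs, kmer_index, k) {
  if (length(seqs) == 0L) return(logical(0))
  hit <- function(ss) {
    n <- nchar(ss)
    ok <- n >= k
    res <- rep(FALSE, length(ss))
    if (!any(ok)) return(res)
    idx <- which(ok)
    nk <- n[idx] - k + 1L
    read_of <- rep(idx, nk)
    starts <- unlist(lapply(nk, seq_len), use.names = FALSE)
    km <- substring(ss[read_of], starts, starts + k - 1L)
    in_idx <- km %chin% kmer_index
    if (any(in_idx)) res[unique(read_of[in_idx])] <- TRUE
    res
  }
  hit(seqs) | hit(revcomp(seqs))
}

#' Write extracted reads to paired FASTQ files
#'
#' Restores sequencing orientation (reverse-strand alignments are
#' reverse-complemented back, with reversed qualities). Orphan reads go to
#' `<prefix>_orphans.fastq`.
#'
#' @param reads a `read_set`.
#' @param out_prefix path prefix for `<prefix>_R1.fastq` / `_R2.fastq`.
#' @return named vector of file paths, with counts as an attribute.
#' @export
reads_to_fastq <- function(reads, out_prefix) {
  rs <- as.data.table(reads)
  if (nrow(rs) == 0L) stop("empty read set")
  seqs <- rs$seq
  quals <- rs$qual
  rev <- which(rs$reverse)
  if (length(rev) > 0L) {
    seqs[rev] <- revcomp(seqs[rev])
    quals[rev] <- reverse_string(quals[rev])
  }
  rs2 <- data.table(name = rs$name, read_index = rs$read_index,
                    seq = seqs, qual = quals)
  cnt <- rs2[, .N, by = name]
  paired <- cnt$name[cnt$N == 2L]
  write_one <- function(dt, path) {
    if (nrow(dt) == 0L) { file.create(path); return(0L) }
    setorder(dt, name)
    lines <- as.vector(rbind(paste0("@", dt$name, "/", dt$read_index),
                             dt$seq, "+", dt$qual))
    writeLines(lines, path)
    nrow(dt)
  }
  f1 <- paste0(out_prefix, "_R1.fastq")
  f2 <- paste0(out_prefix, "_R2.fastq")
  fo <- paste0(out_prefix, "_orphans.fastq")
  n1 <- write_one(rs2[name %chin% paired & read_index == 1L], f1)
  n2 <- write_one(rs2[name %chin% paired & read_index == 2L], f2)
  no <- write_one(rs2[!name %chin% paired], fo)
  out <- c(R1 = f1, R2 = f2, orphans = fo)
  attr(out, "counts") <- c(R1 = n1, R2 = n2, orphans = no)
  out
}
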