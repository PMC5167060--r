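#' Simulation configuration
#'
#' Bundles all parameters of the synthetic repertoire generator with
#' defaults emulating a desk-scale IgH simulation: a random germline of
#' 20 V / 6 D / 5 J / 3 C segments, V(D)J recombination with junctional
#' trimming (0-5 nt) and non-templated insertions (0-10 nt), somatic
#' hypermutation at 2% per V-region base, 2x50 bp paired reads at a mean
#' fragment length of 180 +/- 30 with 0.2% base errors, plus mapped decoy
#' background pairs.
#'
#' @param seed integer seed; every generator operation is deterministic
#'   under it.
#' @param n_v,n_d,n_j,n_c segment counts per class.
#' @param v_len,d_len,j_len length ranges (`c(min, max)`).
#' @param c_len constant-segment length.
#' @param n_clonotypes clonotypes to recombine.
#' @param depth mean per-base read depth per clonotype; length 1 (shared) or
#'   `n_clonotypes` (per clone).
#' @param shm_rate somatic hypermutation substitutions per V-region base.
#' @param trim_max maximum exonuclease trim per junction side.
#' @param insert_range junctional N-nucleotide insertion length range.
#' @param read_len read length.
#' @param frag_mean,frag_sd fragment length distribution.
#' @param seq_error_rate per-base sequencing error rate.
#' @param base_qual,error_qual Phred qualities written for correct/errored
#'   bases.
#' @param n_background decoy (non-BCR) read pairs, mapped to a decoy
#'   reference in the SAM output.
#' @param chain chain to simulate (IGH supported).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_v = 20L, n_d = 6L, n_j = 5L, n_c = 3L,
                       v_len = c(220L, 250L), d_len = c(10L, 20L),
                       j_len = c(45L, 55L), c_len = 180L,
                       n_clonotypes = 30L, depth = 50,
                       shm_rate = 0.02, trim_max = 5L,
                       insert_range = c(0L, 10L), read_len = 50L,
                       frag_mean = 180, frag_sd = 30,
                       seq_error_rate = 0.002, base_qual = 35L,
                       error_qual = 12L, n_background = 500L,
                       chain = "IGH") {
  stopifnot(shm_rate >= 0, shm_rate <= 1, seq_error_rate >= 0,
            seq_error_rate <= 1, read_len > 0, all(v_len > 0))
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic germline database
#'
#' Random segments at uniform base composition, constructed so that
#' recombination yields detectable CDR3s: every V carries an in-frame
#' conserved cysteine codon (TGT) 9 nt from its 3' end (so trims up to
#' 6 nt spare it), and every J carries the conserved tryptophan codon
#' (TGG, IGH) 12 nt from its 5' start. Deterministic under the seed.
#'
#' @param cfg a `sim_config`.
#' @return a `germline_db`.
#' @export
simulate_germline <- function(cfg) {
  if (cfg$n_v < 1L) stop("n_v must be >= 1")
  if (cfg$n_j < 1L) stop("n_j must be >= 1")
  set.seed(cfg$seed)
  make_v <- function(i) {
    f <- sample(0:2, 1L)
    target <- sample(cfg$v_len[1]:cfg$v_len[2], 1L)
    m <- max(1L, round((target - f - 9L) / 3L))
    body <- random_dna(3L * m)
    seq <- paste0(random_dna(f), body, "TGT", random_dna(6L))
    list(id = sprintf("%sV%d-1*01", cfg$chain, i), seq = seq, frame = f)
  }
  make_j <- function(i) {
    len <- sample(cfg$j_len[1]:cfg$j_len[2], 1L)
    seq <- paste0(random_dna(12L), "TGG", random_dna(len - 15L))
    list(id = sprintf("%sJ%d*01", cfg$chain, i), seq = seq)
  }
  vs <- lapply(seq_len(cfg$n_v), make_v)
  ds <- lapply(seq_len(cfg$n_d), function(i)
    list(id = sprintf("%sD%d*01", cfg$chain, i),
         seq = random_dna(sample(cfg$d_len[1]:cfg$d_len[2], 1L))))
  js <- lapply(seq_len(cfg$n_j), make_j)
  iso <- c("IGHM", "IGHG", "IGHA", "IGHD", "IGHE")
  cs <- lapply(seq_len(cfg$n_c), function(i)
    list(id = paste0(iso[(i - 1L) %% length(iso) + 1L], "*01"),
         seq = random_dna(cfg$c_len)))
  segments <- rbindlist(list(
    data.table(id = vapply(vs, `[[`, "", "id"), seg_class = "V",
               sequence = vapply(vs, `[[`, "", "seq"),
               frame_offset = vapply(vs, function(x) as.integer(x$frame), 1L)),
    data.table(id = vapply(ds, `[[`, "", "id"), seg_class = "D",
               sequence = vapply(ds, `[[`, "", "seq"), frame_offset = NA_integer_),
    data.table(id = vapply(js, `[[`, "", "id"), seg_class = "J",
               sequence = vapply(js, `[[`, "", "seq"), frame_offset = NA_integer_),
    data.table(id = vapply(cs, `[[`, "", "id"), seg_class = "C",
               sequence = vapply(cs, `[[`, "", "seq"), frame_offset = NA_integer_)
  ))
  segments[, chain := cfg$chain]
  segments[, functional := TRUE]
  data.table::setcolorder(segments, c("id", "chain", "seg_class", "sequence",
                                      "functional", "frame_offset"))
  structure(list(segments = segments, chain = cfg$chain), class = "germline_db")
}

#' Recombine clonotypes from a germline database
#'
#' Per clonotype: a uniform V/D/J/C draw, 5'/3' exonuclease trims, random
#' N-nucleotide junction insertions (the second insertion is extended by
#' 0-2 nt to keep the conserved J tryptophan in the V reading frame),
#' somatic hypermutation over the V region (sparing the conserved cysteine
#' codon), and a constant-segment suffix. Combinations producing a stop
#' codon or an out-of-window CDR3 are resampled; sequences are unique.
#'
#' @param cfg a `sim_config`.
#' @param db a `germline_db` (from [simulate_germline()] or loaded).
#' @param vj_pairs optional 2-column matrix/data.frame of (v_id, j_id) to
#'   force specific combinations (recycled over clonotypes).
#' @return a `truth_set`: data.table with `id`, `seq`, `v_id`, `d_id`,
#'   `j_id`, `c_id`, `cdr3_aa`, `n_shm`, `depth`.
#' @export
recombine <- function(cfg, db, vj_pairs = NULL) {
  set.seed(cfg$seed + 1L)
  segs <- db$segments
  vset <- segs[seg_class == "V"]
  dset <- segs[seg_class == "D"]
  jset <- segs[seg_class == "J"]
  cset <- segs[seg_class == "C"]
  depth <- rep(cfg$depth, length.out = cfg$n_clonotypes)
  out <- vector("list", cfg$n_clonotypes)
  seen <- character(0)
  for (i in seq_len(cfg$n_clonotypes)) {
    for (try in 1:100) {
      if (try == 100L) stop("could not produce an in-frame junction for clonotype ", i)
      if (is.null(vj_pairs)) {
        v <- vset[sample(.N, 1L)]
        j <- jset[sample(.N, 1L)]
      } else {
        pick <- vj_pairs[(i - 1L) %% nrow(vj_pairs) + 1L, ]
        v <- vset[id == as.character(pick[[1]])]
        j <- jset[id == as.character(pick[[2]])]
      }
      d <- dset[sample(.N, 1L)]
      cc <- cset[sample(.N, 1L)]
      lv <- nchar(v$sequence)
      tv <- sample(0:cfg$trim_max, 1L)
      td5 <- sample(0:cfg$trim_max, 1L)
      td3 <- sample(0:cfg$trim_max, 1L)
      tj <- sample(0:cfg$trim_max, 1L)
      ld <- nchar(d$sequence)
      if (td5 + td3 >= ld) next
      n1 <- sample(cfg$insert_range[1]:cfg$insert_range[2], 1L)
      n2 <- sample(cfg$insert_range[1]:cfg$insert_range[2], 1L)
      vp <- substr(v$sequence, 1L, lv - tv)
      dp <- substr(d$sequence, td5 + 1L, ld - td3)
      pos_c <- lv - 9L                              # Cys codon start, 0-based
      # put the J Trp codon (12 nt past the trimmed J start) in the V frame
      pos_w_raw <- nchar(vp) + n1 + nchar(dp) + n2 + (12L - tj)
      n2 <- n2 + (pos_c - pos_w_raw) %% 3L
      jp <- substr(j$sequence, tj + 1L, nchar(j$sequence))
      seq0 <- paste0(vp, random_dna(n1), dp, random_dna(n2), jp, cc$sequence)
      # somatic hypermutation over the V region, sparing the Cys codon
      shm_cand <- setdiff(seq_len(nchar(vp)), (pos_c + 1L):(pos_c + 3L))
      mut <- shm_cand[runif(length(shm_cand)) < cfg$shm_rate]
      seqc <- strsplit(seq0, NULL)[[1]]
      for (p in mut) {
        seqc[p] <- sample(setdiff(c("A", "C", "G", "T"), seqc[p]), 1L)
      }
      seq1 <- paste(seqc, collapse = "")
      pos_w <- nchar(vp) + n1 + nchar(dp) + n2 + (12L - tj)
      cdr3_nt <- substr(seq1, pos_c + 1L, pos_w + 3L)
      if (nchar(cdr3_nt) %% 3L != 0L) next
      aa <- translate_dna(cdr3_nt)
      if (grepl("\\*", aa)) next
      if (nchar(aa) < 5L || nchar(aa) > 38L) next
      if (seq1 %chin% seen) next
      seen <- c(seen, seq1)
      out[[i]] <- data.table(id = sprintf("truth%03d", i), seq = seq1,
                             v_id = v$id, d_id = d$id, j_id = j$id,
                             c_id = cc$id, cdr3_aa = aa,
                             n_shm = length(mut), depth = depth[i])
      break
    }
  }
  truth <- rbindlist(out)
  class(truth) <- c("truth_set", class(truth))
  truth
}

#' Generate paired short reads from a truth set
#'
#' Fragments are placed uniformly along each clonotype so that the mean
#' per-base depth matches its simulated depth; paired `read_len` reads are
#' taken from the fragment ends (R2 reverse-complemented), sequencing
#' errors are substituted per base at `seq_error_rate` with matching
#' quality strings, and decoy background pairs are appended. All
#' BCR-derived reads are unmapped in the SAM output; decoys are mapped to
#' the decoy reference.
#'
#' @param truth a `truth_set` from [recombine()].
#' @param cfg a `sim_config`.
#' @return a `sim_reads` list: `reads` (data.table `name`, `read_index`,
#'   `seq`, `qual`, `clone`), `decoys` (data.table with mapping info),
#'   `decoy_ref` (named character), `truth` (the input).
#' @export
generate_reads <- function(truth, cfg) {
  if (nrow(truth) == 0L) stop("empty truth set")
  set.seed(cfg$seed + 2L)
  rl <- cfg$read_len
  one_clone <- function(tid, seq, depth) {
    L <- nchar(seq)
    if (L < 2L * rl + 10L) stop("clonotype ", tid, " shorter than a fragment")
    n_pairs <- max(1L, round(depth * L / (2 * rl)))
    flen <- pmin(pmax(round(rnorm(n_pairs, cfg$frag_mean, cfg$frag_sd)),
                      2L * rl + 10L), L)
    start <- floor(runif(n_pairs, 0, L - flen + 1))   # 0-based
    r1 <- substring(seq, start + 1L, start + rl)
    r2 <- revcomp(substring(seq, start + flen - rl + 1L, start + flen))
    data.table(name = sprintf("%s:%05d", tid, seq_len(n_pairs)),
               clone = tid,
               r1 = r1, r2 = r2)
  }
  frag <- rbindlist(Map(one_clone, truth$id, truth$seq, truth$depth))
  reads <- rbindlist(list(
    data.table(name = frag$name, read_index = 1L, seq = frag$r1, clone = frag$clone),
    data.table(name = frag$name, read_index = 2L, seq = frag$r2, clone = frag$clone)
  ))
  err <- apply_errors(reads$seq, cfg)
  reads[, seq := err$seq]
  reads[, qual := err$qual]
  decoy_ref <- setNames(random_dna(2000L), "decoy1")
  decoys <- NULL
  if (cfg$n_background > 0L) {
    dl <- nchar(decoy_ref)
    flen <- pmin(pmax(round(rnorm(cfg$n_background, cfg$frag_mean, cfg$frag_sd)),
                      2L * rl + 10L), dl)
    start <- floor(runif(cfg$n_background, 0, dl - flen + 1))
    d1 <- substring(decoy_ref, start + 1L, start + rl)
    d2 <- substring(decoy_ref, start + flen - rl + 1L, start + flen)
    e1 <- apply_errors(d1, cfg)
    e2 <- apply_errors(d2, cfg)
    decoys <- data.table(
      name = sprintf("decoy:%05d", seq_len(cfg$n_background)),
      pos1 = start + 1L, pos2 = start + flen - rl + 1L, flen = flen,
      seq1 = e1$seq, qual1 = e1$qual, seq2 = e2$seq, qual2 = e2$qual
    )
  }
  structure(list(reads = reads, decoys = decoys, decoy_ref = decoy_ref,
                 truth = truth, cfg = cfg),
            class = "sim_reads")
}

# substitute sequencing errors and build matching quality strings
apply_errors <- function(seqs, cfg) {
  n <- nchar(seqs)
  qual <- vapply(n, function(k) strrep(rawToChar(as.raw(cfg$base_qual + 33L)), k),
                 character(1))
  if (cfg$seq_error_rate > 0) {
    chars <- strsplit(seqs, NULL)
    qchar <- strsplit(qual, NULL)
    eq <- rawToChar(as.raw(cfg$error_qual + 33L))
    for (i in seq_along(chars)) {
      hit <- which(runif(n[i]) < cfg$seq_error_rate)
      for (p in hit) {
        chars[[i]][p] <- sample(setdiff(c("A", "C", "G", "T"), chars[[i]][p]), 1L)
        qchar[[i]][p] <- eq
      }
      if (length(hit) > 0L) {
        seqs[i] <- paste(chars[[i]], collapse = "")
        qual[i] <- paste(qchar[[i]], collapse = "")
      }
    }
  }
  list(seq = seqs, qual = qual)
}

#' Write a simulated dataset to disk
#'
#' Emits the SAM (BCR reads unmapped, decoys mapped to the decoy
#' reference), paired FASTQ, truth FASTA/TSV and germline FASTA/TSV.
#'
#' @param sim a `sim_reads` from [generate_reads()].
#' @param db the `germline_db` used for recombination.
#' @param dir output directory (created).
#' @return named vector of file paths.
#' @export
write_sim <- function(sim, db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sam <- file.path(dir, "reads.sam")
  con <- file(sam, "w")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:decoy1\tLN:", nchar(sim$decoy_ref)),
               "@PG\tID:igasm-sim\tPN:igasm-sim"), con)
  r <- sim$reads
  flag <- ifelse(r$read_index == 1L, 77L, 141L)
  writeLines(paste(r$name, flag, "*", 0L, 0L, "*", "*", 0L, 0L,
                   r$seq, r$qual, sep = "\t"), con)
  d <- sim$decoys
  if (!is.null(d) && nrow(d) > 0L) {
    writeLines(paste(d$name, 99L, "decoy1", d$pos1, 60L,
                     paste0(nchar(d$seq1), "M"), "=", d$pos2, d$flen,
                     d$seq1, d$qual1, sep = "\t"), con)
    writeLines(paste(d$name, 147L, "decoy1", d$pos2, 60L,
                     paste0(nchar(d$seq2), "M"), "=", d$pos1, -d$flen,
                     revcomp(d$seq2), reverse_string(d$qual2), sep = "\t"), con)
  }
  close(con)
  fq1 <- file.path(dir, "reads_R1.fastq")
  fq2 <- file.path(dir, "reads_R2.fastq")
  for (ri in 1:2) {
    dt <- r[read_index == ri]
    writeLines(as.vector(rbind(paste0("@", dt$name, "/", ri), dt$seq, "+",
                               dt$qual)), if (ri == 1L) fq1 else fq2)
  }
  truth_fa <- file.path(dir, "truth.fasta")
  write_fasta(setNames(sim$truth$seq, sim$truth$id), truth_fa)
  truth_tsv <- file.path(dir, "truth.tsv")
  fwrite(sim$truth[, .(id, v_id, d_id, j_id, c_id, cdr3_aa, n_shm, depth)],
         truth_tsv, sep = "\t")
  germ_fa <- file.path(dir, "germline.fasta")
  germ_tsv <- file.path(dir, "germline.tsv")
  write_germline(db, germ_fa, germ_tsv)
  c(sam = sam, fastq_r1 = fq1, fastq_r2 = fq2, truth_fasta = truth_fa,
    truth_tsv = truth_tsv, germline_fasta = germ_fa, germline_meta = germ_tsv)
}

#' Evaluate assembled contigs against a simulated truth set
#'
#' A truth clonotype is detected when an accepted contig matches it
#' ungapped (either strand) with at most `max_mm` mismatches over the full
#' contig length; a contig matching no clonotype at that threshold is a
#' false positive. Abundance agreement is the squared Pearson correlation
#' between summed per-clonotype contig abundances and simulated depths,
#' over detected clonotypes.
#'
#' @param contigs data.table with `id`, `seq` and optionally `abundance`.
#' @param truth a `truth_set` (columns `id`, `seq`, `depth`).
#' @param max_mm mismatch allowance for detection (default 0; metrics are
#'   also reported at 2 mismatches).
#' @param frag_len nominal fragment length used to convert per-contig
#'   fragment counts into densities for the abundance comparison (counts
#'   divided by placeable fragment start positions, so contigs of unequal
#'   confirmed span stay comparable; default 180).
#' @return list with `sensitivity`, `sensitivity_2mm`, `false_positives`,
#'   `n_truth`, `n_detected`, `r_squared`, `assignments` (contig ->
#'   clonotype), `per_clone` (data.table).
#' @export
evaluate_assembly <- function(contigs, truth, max_mm = 0L,
                              frag_len = 180) {
  ct <- as.data.table(contigs)
  n_truth <- nrow(truth)
  if (nrow(ct) == 0L) {
    return(list(sensitivity = 0, sensitivity_2mm = 0, false_positives = 0L,
                n_truth = n_truth, n_detected = 0L, r_squared = NA_real_,
                assignments = data.table(contig_id = character(0),
                                         truth_id = character(0),
                                         mismatches = integer(0)),
                per_clone = data.table(truth_id = truth$id, depth = truth$depth,
                                       detected = FALSE, est_abundance = 0)))
  }
  best <- rbindlist(lapply(seq_len(nrow(ct)), function(i) {
    fw <- .best_window_mismatch(truth$seq, ct$seq[i], stop_at = 0L)
    rv <- .best_window_mismatch(truth$seq, revcomp(ct$seq[i]), stop_at = 0L)
    mm <- pmin(ifelse(is.na(fw$mismatches), .Machine$integer.max, fw$mismatches),
               ifelse(is.na(rv$mismatches), .Machine$integer.max, rv$mismatches))
    k <- which.min(mm)
    data.table(contig_id = ct$id[i], truth_id = truth$id[k],
               mismatches = mm[k])
  }))
  det <- function(mm_cut) unique(best$truth_id[best$mismatches <= mm_cut])
  detected <- det(max_mm)
  fp <- sum(best$mismatches > max_mm)
  ab <- if ("abundance" %chin% names(ct))
    setNames(ct$abundance, ct$id) else setNames(rep(1, nrow(ct)), ct$id)
  # density: expected fragments per placeable start position
  ab <- ab / pmax(nchar(ct$seq) - frag_len + 1, 1)[match(names(ab), ct$id)]
  hits <- best[mismatches <= max_mm]
  est <- hits[, .(est = sum(ab[contig_id])), by = truth_id]
  per_clone <- data.table(truth_id = truth$id, depth = truth$depth)
  per_clone[, detected := truth_id %chin% detected]
  per_clone[, est_abundance := 0]
  per_clone[est, est_abundance := i.est, on = "truth_id"]
  dsub <- per_clone[detected == TRUE]
  r2 <- if (nrow(dsub) >= 3L && stats::sd(dsub$depth) > 0 &&
            stats::sd(dsub$est_abundance) > 0)
    cor(dsub$est_abundance, dsub$depth)^2 else NA_real_
  list(sensitivity = length(detected) / n_truth,
       sensitivity_2mm = length(det(2L)) / n_truth,
       false_positives = fp, n_truth = n_truth,
       n_detected = length(detected), r_squared = r2,
       assignments = best, per_clone = per_clone)
}
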