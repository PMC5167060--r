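# anchor scanning, CDR3 location, perfect-pair mapping and contig filters

make_junction_contig <- function() {
  # germline-style V with Cys 9 nt from its 3' end, J with Trp at offset 12
  set.seed(5)
  v <- paste0(paste(sample(c("A","C","G","T"), 99, replace = TRUE),
                    collapse = ""), "TGT", "AACCGG")    # 108 nt, frame 0
  # force in-frame: Cys codon starts at 0-based 99 (99 %% 3 == 0)
  j <- paste0("ACGTACGTACGT", "TGG", paste(sample(c("A","C","G","T"), 36,
                                                  replace = TRUE),
                                           collapse = ""))
  cst <- strrep("TTGACA", 20)
  # junction: trim 2 from V 3', insert 4 nt, trim 3 from J 5'
  vp <- substr(v, 1, nchar(v) - 2)
  jp <- substr(j, 4, nchar(j))
  ins_len <- 4L
  # keep J Trp in V frame: distance Cys->Trp must be divisible by 3
  pos_c <- 99L
  pos_w0 <- nchar(vp) + ins_len + (12L - 3L)
  ins_len <- ins_len + (pos_c - pos_w0) %% 3L
  ins <- paste(sample(c("A","C","G","T"), ins_len, replace = TRUE),
               collapse = "")
  contig <- paste0(vp, ins, jp, cst)
  list(contig = contig, v = v, j = j, cst = cst, pos_c = pos_c,
       pos_w = nchar(vp) + ins_len + (12L - 3L))
}

tiny_anchor_set <- function(v, j, v_end_offset = 8L, j_start_offset = 8L) {
  d <- tempfile(); dir.create(d)
  writeLines(c(">V1", v, ">J1", j), file.path(d, "g.fa"))
  writeLines(c("id\tchain\tclass\tfunctional\tframe_offset",
               "V1\tIGH\tV\tTRUE\t0", "J1\tIGH\tJ\tTRUE\tNA"),
             file.path(d, "g.tsv"))
  db <- load_germline(file.path(d, "g.fa"), file.path(d, "g.tsv"))
  list(db = db,
       anchors = extract_anchors(db, v_end_offset = v_end_offset,
                                 j_start_offset = j_start_offset))
}

test_that("anchor search equals a brute-force Hamming scan", {
  fx <- make_junction_contig()
  ta <- tiny_anchor_set(fx$v, fx$j)
  hits <- find_anchor_hits(fx$contig, ta$anchors, max_mm = 4L)
  expect_gt(nrow(hits), 0L)
  for (i in seq_len(nrow(hits))) {
    mm <- oracle_hamming_scan(fx$contig, hits$anchor[i])
    expect_equal(hits$mismatches[i], mm[hits$pos[i] + 1L])
    expect_lte(hits$mismatches[i], 4L)
  }
  # an anchor with five substitutions is not reported
  a5 <- strsplit(ta$anchors$v_anchors$anchor[1], NULL)[[1]]
  idx <- 1:5
  a5[idx] <- vapply(a5[idx], function(b)
    setdiff(c("A","C","G","T"), b)[1], character(1))
  contig5 <- sub(ta$anchors$v_anchors$anchor[1], paste(a5, collapse = ""),
                 fx$contig, fixed = TRUE)
  h5 <- find_anchor_hits(contig5, ta$anchors, max_mm = 4L)
  expect_false(any(h5$anchor_class == "V"))
  # reverse-strand-only anchors are not found (orientation fixed upstream)
  hrc <- find_anchor_hits(oracle_revcomp(fx$contig), ta$anchors, max_mm = 0L)
  expect_equal(nrow(hrc[hrc$mismatches == 0L]), 0L)
})

test_that("CDR3 location fixes frame from the V anchor and translates", {
  fx <- make_junction_contig()
  ta <- tiny_anchor_set(fx$v, fx$j)
  hits <- find_anchor_hits(fx$contig, ta$anchors)
  best <- attr(hits, "best")
  call <- locate_cdr3(fx$contig, best$v, best$j, chain = "IGH",
                      v_frame_offset = 0L, v_seg_len = nchar(fx$v))
  expect_false(is.null(call))
  expect_equal(call$nt_start, fx$pos_c)
  expect_equal(call$nt_end, fx$pos_w + 2L)
  aa <- oracle_translate(call$nt_sequence)
  expect_equal(call$aa_sequence, aa)
  expect_equal(substr(aa, 1, 1), "C")
  expect_equal(substr(aa, nchar(aa), nchar(aa)), "W")
  expect_equal((call$nt_end - call$nt_start + 1L) %% 3L, 0L)

  # out-of-frame Cys is rejected: shift the claimed frame offset by one
  bad <- locate_cdr3(fx$contig, best$v, best$j, chain = "IGH",
                     v_frame_offset = 1L, v_seg_len = nchar(fx$v))
  expect_true(is.null(bad) || bad$nt_start != fx$pos_c)

  # amino-acid window rule rejects spans outside the configured range
  expect_null(locate_cdr3(fx$contig, best$v, best$j, chain = "IGH",
                          v_frame_offset = 0L, v_seg_len = nchar(fx$v),
                          aa_window = c(30L, 38L)))
})

test_that("perfect pair mapping requires exact, opposed, spaced mates", {
  fx <- make_junction_contig()
  contig <- substr(fx$contig, 1, 200)
  r1 <- substr(contig, 1, 50)
  r2 <- oracle_revcomp(substr(contig, 61, 110))   # insert 110
  reads <- data.table::data.table(
    name = c("p", "p", "q", "q", "r", "r"),
    read_index = c(1L, 2L, 1L, 2L, 1L, 2L),
    seq = c(r1, r2,
            sub("A", "G", r1), r2,                # one mismatch: not mapped
            r1, substr(contig, 61, 110)))         # both forward: not mapped
  ev <- map_reads_perfect(reads, contig, min_insert = 50L, max_insert = 500L)
  expect_equal(ev$n_pairs, 1L)
  expect_equal(ev$pairs$name, "p")
  expect_equal(ev$pairs$fwd_pos, 0L)
  expect_equal(ev$pairs$rev_pos, 60L)
  expect_equal(ev$pairs$insert, 110L)
  # depth: two 50-mers
  expect_equal(sum(ev$depth), 100L)
  expect_equal(ev$depth[1], 1L)
  expect_equal(ev$depth[55], 0L)
  # insert outside the window excludes the pair
  ev2 <- map_reads_perfect(reads[1:2], contig, min_insert = 150L,
                           max_insert = 500L)
  expect_equal(ev2$n_pairs, 0L)
})

test_that("depth vector sums to twice pair count times read length", {
  fx <- make_junction_contig()
  contig <- substr(fx$contig, 1, 240)
  mk <- function(i, s, flen) {
    data.table::data.table(
      name = rep(sprintf("p%02d", i), 2), read_index = 1:2,
      seq = c(substr(contig, s, s + 49),
              oracle_revcomp(substr(contig, s + flen - 50, s + flen - 1))))
  }
  set.seed(9)
  reads <- data.table::rbindlist(
    lapply(1:12, function(i) mk(i, sample(1:60, 1), sample(120:180, 1))))
  ev <- map_reads_perfect(reads, contig)
  expect_equal(ev$n_pairs, 12L)
  expect_equal(sum(ev$depth), 2L * 12L * 50L)
})

test_that("contig filters enforce support, contiguity and uniqueness", {
  fx <- make_junction_contig()
  contig <- fx$contig
  L <- nchar(contig)
  # dense pair tiling across the whole contig (insert 110)
  mk_pairs <- function(cseq, n, prefix) {
    L <- nchar(cseq)
    starts <- floor(seq(0, L - 111, length.out = n))
    data.table::rbindlist(lapply(seq_len(n), function(i) {
      s <- starts[i]
      data.table::data.table(
        name = rep(sprintf("%s%03d", prefix, i), 2), read_index = 1:2,
        seq = c(substr(cseq, s + 1, s + 50),
                oracle_revcomp(substr(cseq, s + 61, s + 110))))
    }))
  }
  reads <- mk_pairs(contig, 60, "a")
  ta <- tiny_anchor_set(fx$v, fx$j)
  hits <- find_anchor_hits(contig, ta$anchors)
  best <- attr(hits, "best")
  contigs <- data.table::data.table(
    id = "c1", seq = contig, path_score = 1.0, source = "s", truncated = FALSE,
    v_pos = best$v$pos, j_end = best$j$pos + 15L)
  ev <- list(map_reads_perfect(reads, contig))
  acc <- filter_contigs(contigs, ev, min_pairs = 10L, min_unique_pairs = 2L,
                        min_contig_len = 150L)
  expect_equal(nrow(acc), 1L)
  expect_gte(acc$unique_pairs, 2L)

  # a sparse read set fails the pair threshold
  acc2 <- filter_contigs(contigs, list(map_reads_perfect(reads[1:8], contig)),
                         min_pairs = 10L, min_contig_len = 150L)
  expect_equal(nrow(acc2), 0L)

  # identical duplicate contigs collapse to one record
  contigs3 <- data.table::rbindlist(list(contigs, contigs))
  contigs3$id <- c("c1", "c2")
  ev3 <- list(map_reads_perfect(reads, contig), map_reads_perfect(reads, contig))
  acc3 <- filter_contigs(contigs3, ev3, min_pairs = 10L,
                         min_unique_pairs = 0L, min_contig_len = 150L)
  expect_equal(nrow(acc3), 1L)

  # a contig whose tail has no junction-anchored pair support is trimmed
  tail_ext <- paste0(contig, strrep("ACGT", 15))
  reads_noext <- mk_pairs(contig, 60, "b")
  contigs4 <- data.table::copy(contigs)
  contigs4$seq <- tail_ext
  ev4 <- list(map_reads_perfect(reads_noext, tail_ext))
  acc4 <- filter_contigs(contigs4, ev4, min_pairs = 10L,
                         min_unique_pairs = 2L, min_contig_len = 150L)
  expect_equal(nrow(acc4), 1L)
  expect_lte(nchar(acc4$seq), nchar(contig))
})
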