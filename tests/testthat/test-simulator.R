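# synthetic germline, V(D)J recombination, read generation, evaluation

test_that("germline simulation is seed-deterministic and well-formed", {
  cfg <- sim_config(seed = 17, n_v = 8, n_d = 3, n_j = 2, n_c = 2)
  db1 <- simulate_germline(cfg)
  db2 <- simulate_germline(cfg)
  expect_identical(db1$segments, db2$segments)
  vs <- db1$segments[db1$segments$seg_class == "V"]
  # every V carries an in-frame TGT 9 nt from its 3' end
  for (i in seq_len(nrow(vs))) {
    s <- vs$sequence[i]; L <- nchar(s)
    expect_equal(substr(s, L - 8L, L - 6L), "TGT")
    expect_equal((L - 9L - vs$frame_offset[i]) %% 3L, 0L)
  }
  js <- db1$segments[db1$segments$seg_class == "J"]
  expect_true(all(substr(js$sequence, 13L, 15L) == "TGG"))
  expect_error(simulate_germline(sim_config(n_v = 0L)), "n_v")
})

test_that("recombination with no edits concatenates V+D+J+C literally", {
  # hand-built germline where V|D|J is already in frame (no n2 adjustment)
  d <- tempfile(); dir.create(d)
  v <- paste0(strrep("ACG", 32), "TGT", "AACCGG")      # 105 nt, frame 0
  dd <- "GGGTTTCCC"                                    # 9 nt
  # distance Cys->Trp = (105-96) + 0 + 9 + 0 + 12 = 30, divisible by 3
  j <- paste0("ACGTACGTACGT", "TGG", strrep("CATG", 9))
  cc <- strrep("TTGACA", 40)
  writeLines(c(">V1", v, ">D1", dd, ">J1", j, ">C1", cc), file.path(d, "g.fa"))
  writeLines(c("id\tchain\tclass\tfunctional\tframe_offset",
               "V1\tIGH\tV\tTRUE\t0", "D1\tIGH\tD\tTRUE\tNA",
               "J1\tIGH\tJ\tTRUE\tNA", "C1\tIGH\tC\tTRUE\tNA"),
             file.path(d, "g.tsv"))
  db <- load_germline(file.path(d, "g.fa"), file.path(d, "g.tsv"))
  cfg <- sim_config(seed = 3, n_clonotypes = 1, shm_rate = 0,
                    trim_max = 0L, insert_range = c(0L, 0L))
  truth <- recombine(cfg, db)
  expect_equal(truth$seq, paste0(v, dd, j, cc))
  expect_equal(truth$n_shm, 0L)
  aa <- oracle_translate(substr(truth$seq, 97, 129))
  expect_equal(truth$cdr3_aa, aa)
})

test_that("forced V/J combinations produce the full grid of clonotypes", {
  cfg <- sim_config(seed = 23, n_v = 3, n_d = 2, n_j = 2, n_clonotypes = 60)
  db <- simulate_germline(cfg)
  vs <- db$segments[db$segments$seg_class == "V", id]
  js <- db$segments[db$segments$seg_class == "J", id]
  grid <- expand.grid(v = vs, j = js, stringsAsFactors = FALSE)
  truth <- recombine(cfg, db, vj_pairs = grid)
  # ten clonotypes per V/J combination
  tab <- table(truth$v_id, truth$j_id)
  expect_true(all(tab == 10L))
  expect_equal(nrow(truth), 10L * nrow(grid))
})

test_that("recombination is deterministic and produces unique clonotypes", {
  cfg <- sim_config(seed = 31, n_clonotypes = 12)
  db <- simulate_germline(cfg)
  t1 <- recombine(cfg, db)
  t2 <- recombine(cfg, db)
  expect_identical(t1, t2)
  expect_equal(anyDuplicated(t1$seq), 0L)
  # conserved flanks survive SHM: first CDR3 residue C, last W
  expect_true(all(startsWith(t1$cdr3_aa, "C")))
  expect_true(all(endsWith(t1$cdr3_aa, "W")))
})

test_that("read generation hits the requested depth and is deterministic", {
  cfg <- sim_config(seed = 41, n_clonotypes = 4, depth = 50,
                    seq_error_rate = 0)
  db <- simulate_germline(cfg)
  truth <- recombine(cfg, db)
  sim1 <- generate_reads(truth, cfg)
  sim2 <- generate_reads(truth, cfg)
  expect_identical(sim1$reads, sim2$reads)
  # pair count per clone matches depth * L / (2 * read_len)
  pairs_per <- table(sim1$reads$clone) / 2
  want <- round(50 * nchar(truth$seq) / 100)
  expect_equal(unname(as.integer(pairs_per[truth$id])), as.integer(want))
  # with no errors every read is an exact substring of its clone
  for (i in sample(nrow(sim1$reads), 50)) {
    r <- sim1$reads[i]
    src <- truth[truth$id == r$clone, seq]
    expect_true(grepl(r$seq, src, fixed = TRUE) ||
                grepl(oracle_revcomp(r$seq), src, fixed = TRUE))
  }
})

test_that("written SAM and FASTQ round-trip through the extractor", {
  cfg <- sim_config(seed = 43, n_clonotypes = 2, depth = 20,
                    n_background = 25)
  db <- simulate_germline(cfg)
  truth <- recombine(cfg, db)
  sim <- generate_reads(truth, cfg)
  dir <- tempfile()
  files <- write_sim(sim, db, dir)
  expect_true(all(file.exists(files)))
  # determinism at the byte level
  files2 <- write_sim(sim, db, tempfile())
  expect_identical(readLines(files[["sam"]]), readLines(files2[["sam"]]))
  expect_identical(readLines(files[["truth_fasta"]]),
                   readLines(files2[["truth_fasta"]]))
  reads <- read_alignments(files[["sam"]])
  expect_equal(nrow(reads), nrow(sim$reads) + 2L * cfg$n_background)
  # BCR reads are unmapped, decoys mapped
  expect_equal(sum(!reads$mapped), nrow(sim$reads))
  gdb <- load_germline(files[["germline_fasta"]], files[["germline_meta"]])
  idx <- build_kmer_index(gdb)
  cand <- extract_candidate_reads(reads, NULL, idx)
  # all simulated BCR reads extracted; decoys excluded unless rescued
  expect_gte(nrow(cand), nrow(sim$reads))
  expect_lt(nrow(cand), nrow(reads))
})

test_that("evaluation counts detections, false positives and abundance fit", {
  cfg <- sim_config(seed = 47, n_clonotypes = 10)
  db <- simulate_germline(cfg)
  truth <- recombine(cfg, db)
  contigs <- data.table::data.table(
    id = sprintf("c%02d", 1:9),
    seq = substr(truth$seq[1:9], 11, 370),
    abundance = truth$depth[1:9] * 2.5)
  ev <- evaluate_assembly(contigs, truth)
  expect_equal(ev$sensitivity, 0.9)
  expect_equal(ev$false_positives, 0L)
  # a contig matching nothing is one false positive
  contigs2 <- data.table::rbindlist(list(
    contigs, data.table::data.table(id = "junk", seq = strrep("ACGGT", 72),
                                    abundance = 1)))
  ev2 <- evaluate_assembly(contigs2, truth)
  expect_equal(ev2$false_positives, 1L)
  # abundances exactly proportional to depth give r-squared 1
  cfg3 <- sim_config(seed = 47, n_clonotypes = 10,
                     depth = rep(c(25, 50, 100, 250, 500), 2))
  truth3 <- recombine(cfg3, db)
  contigs3 <- data.table::data.table(
    id = sprintf("c%02d", 1:10), seq = substr(truth3$seq, 6, 365),
    abundance = truth3$depth * 3.1)
  ev3 <- evaluate_assembly(contigs3, truth3)
  expect_equal(ev3$r_squared, 1.0, tolerance = 1e-9)
  # two-mismatch detection convention is also reported
  mut <- strsplit(contigs$seq[1], NULL)[[1]]
  mut[c(50, 90)] <- c("A", "A")
  contigs4 <- data.table::copy(contigs)
  contigs4$seq[1] <- paste(mut, collapse = "")
  ev4 <- evaluate_assembly(contigs4, truth)
  expect_lte(ev4$sensitivity, ev4$sensitivity_2mm)
})
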