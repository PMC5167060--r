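#' Parameter profiles for standard and sensitive modes
#'
#' Sensitive mode uses a smaller k-mer size, a more exhaustive traversal
#' (lower path-score threshold) and less aggressive pruning and contig
#' filtering than standard mode; the distinct-read pruning rule applies in
#' both.
#'
#' @param mode `"standard"` or `"sensitive"`.
#' @return named list of parameter overrides.
#' @export
mode_profiles <- function(mode = c("standard", "sensitive")) {
  mode <- match.arg(mode)
  if (mode == "standard")
    list(k = 35L, min_path_score = 1e-15, min_count = 2L, min_pairs = 10L)
  else
    list(k = 25L, min_path_score = 1e-18, min_count = 1L, min_pairs = 5L)
}

pipeline_defaults <- function() {
  list(
    chain = "IGH", mode = "standard",
    # graph
    k = 35L, min_count = 2L, min_qual_sum = 60L, min_distinct = 2L,
    # traversal
    min_path_score = 1e-15, max_contig_len = 360L, min_contig_len = 250L,
    min_source_homology = 23L, seed_len = 12L, max_paths_per_source = 10000L,
    max_node_visits = 2L,
    # extraction
    index_k = 15L,
    # anchors / CDR3
    anchor_len = 16L, v_end_offset = 8L, j_start_offset = 8L,
    anchor_max_mm = 4L, max_vj_gap = 150L,
    aa_window_igh = c(5L, 38L), aa_window_light = c(4L, 20L),
    # contig confirmation
    min_insert = 50L, max_insert = 1000L, min_pairs = 10L, min_depth = 2L,
    min_distinct_starts = 5L, max_start_gap = 25L, min_unique_pairs = 3L,
    tail_extent = 80L,
    # postprocessing
    tail_len = 48L, isotype_max_mm = 4L, em_iters = 200L, em_tol = 1e-6
  )
}

#' Build a pipeline configuration
#'
#' Merges, in increasing precedence: package defaults, the mode profile
#' (standard/sensitive), and explicit overrides.
#'
#' @param alignments path to the input SAM/BAM.
#' @param germline_fasta,germline_meta germline segment FASTA and metadata
#'   TSV.
#' @param out_dir output directory.
#' @param loci_bed optional BED of IG locus intervals on the alignment
#'   reference.
#' @param chain chain to assemble.
#' @param mode `"standard"` or `"sensitive"`.
#' @param ... explicit parameter overrides (see [pipeline_defaults
#'   names][mode_profiles()]), e.g. `k = 31`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(alignments, germline_fasta, germline_meta,
                            out_dir = NULL, loci_bed = NULL, chain = "IGH",
                            mode = c("standard", "sensitive"), ...) {
  mode <- match.arg(mode)
  cfg <- pipeline_defaults()
  prof <- mode_profiles(mode)
  cfg[names(prof)] <- prof
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$chain <- chain
  cfg$mode <- mode
  cfg$alignments <- alignments
  cfg$germline_fasta <- germline_fasta
  cfg$germline_meta <- germline_meta
  cfg$loci_bed <- loci_bed
  cfg$out_dir <- out_dir
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  required <- c("alignments", "germline_fasta", "germline_meta")
  miss <- setdiff(required, names(y))
  if (length(miss) > 0L)
    stop("config missing required key(s): ", paste(miss, collapse = ", "))
  fixed <- intersect(names(y), c("alignments", "germline_fasta",
                                 "germline_meta", "out_dir", "loci_bed",
                                 "chain", "mode"))
  args <- y[fixed]
  args <- c(args, y[setdiff(names(y), fixed)])
  do.call(pipeline_config, args)
}

#' Run the assembly pipeline end to end
#'
#' Extract candidate reads, build/prune/condense the de Bruijn graph,
#' traverse from V-homologous sources, confirm contigs by anchors, CDR3
#' and perfect-pair coverage, then assign isotypes and V/J genes, quantify
#' abundance and cluster clonotypes. An empty repertoire is a valid
#' outcome (empty outputs, not an error).
#'
#' @param cfg a `pipeline_config`.
#' @return a `pipeline_result` list: `contigs` (annotated data.table),
#'   `clonotypes`, `summary`, `counts` (per-stage log), `files` (paths
#'   when `out_dir` is set), `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  counts <- list()
  db <- load_germline(cfg$germline_fasta, cfg$germline_meta, chain = cfg$chain)
  idx <- build_kmer_index(db, k = cfg$index_k)
  anchors <- extract_anchors(db, anchor_len = cfg$anchor_len,
                             v_end_offset = cfg$v_end_offset,
                             j_start_offset = cfg$j_start_offset)
  loci <- if (!is.null(cfg$loci_bed)) load_loci(cfg$loci_bed, cfg$chain) else NULL
  reads <- read_alignments(cfg$alignments)
  counts$input_reads <- nrow(reads)
  cand <- extract_candidate_reads(reads, loci, idx, k = cfg$index_k)
  counts$extraction <- attr(cand, "extraction_report")
  result <- if (nrow(cand) == 0L) {
    warning("no candidate reads extracted; emitting empty outputs")
    empty_result(counts)
  } else {
    assemble_and_confirm(cand, db, anchors, cfg, counts)
  }
  result$config <- cfg
  if (!is.null(cfg$out_dir)) result$files <- write_outputs(result, cfg)
  class(result) <- "pipeline_result"
  result
}

empty_result <- function(counts) {
  list(contigs = data.table(id = character(0), seq = character(0),
                            path_score = numeric(0), cdr3_aa = character(0),
                            v_gene = character(0), j_gene = character(0),
                            isotype = character(0), v_identity = numeric(0),
                            abundance = numeric(0)),
       clonotypes = cluster_clonotypes(data.table()),
       summary = repertoire_summary(cluster_clonotypes(data.table())),
       mapped_pairs = NULL, counts = counts)
}

assemble_and_confirm <- function(cand, db, anchors, cfg, counts) {
  g <- build_graph(cand, k = cfg$k)
  counts$vertices_raw <- nrow(g$vertices)
  pg <- prune_graph(g, min_count = cfg$min_count,
                    min_qual_sum = cfg$min_qual_sum,
                    min_distinct = cfg$min_distinct)
  counts$vertices_pruned <- nrow(pg$vertices)
  cg <- condense(pg)
  counts$condensed_nodes <- nrow(cg$nodes)
  v_refs <- germline_seqs(db, "V")
  sources <- screen_sources(cg, v_refs, seed_len = cfg$seed_len,
                            min_score = cfg$min_source_homology)
  counts$sources_accepted <- nrow(sources)
  contigs <- traverse(cg, sources, min_path_score = cfg$min_path_score,
                      max_contig_len = cfg$max_contig_len,
                      min_contig_len = cfg$min_contig_len,
                      max_paths_per_source = cfg$max_paths_per_source,
                      max_node_visits = cfg$max_node_visits)
  counts$paths_emitted <- nrow(contigs)
  contigs <- contigs[!duplicated(seq)]
  if (nrow(contigs) == 0L) return(empty_result(counts))

  # anchor + CDR3 gate
  vmeta <- db$segments[seg_class == "V"]
  aa_window <- if (cfg$chain == "IGH") cfg$aa_window_igh else cfg$aa_window_light
  anno <- lapply(seq_len(nrow(contigs)), function(i) {
    hits <- find_anchor_hits(contigs$seq[i], anchors, max_mm = cfg$anchor_max_mm)
    best <- attr(hits, "best")
    if (is.null(best)) return(NULL)
    v_seg_id <- best$v$segments[[1]][1]
    vrow <- vmeta[id == v_seg_id]
    cdr3 <- locate_cdr3(contigs$seq[i], best$v, best$j, chain = cfg$chain,
                        v_frame_offset = vrow$frame_offset,
                        v_seg_len = nchar(vrow$sequence),
                        aa_window = aa_window, max_gap = cfg$max_vj_gap,
                        anchor_len = cfg$anchor_len)
    if (is.null(cdr3)) return(NULL)
    list(i = i, v_pos = best$v$pos, j_end = best$j$pos + cfg$anchor_len - 1L,
         cdr3 = cdr3)
  })
  anno <- anno[!vapply(anno, is.null, logical(1))]
  counts$contigs_with_cdr3 <- length(anno)
  if (length(anno) == 0L) return(empty_result(counts))
  keep_i <- vapply(anno, `[[`, integer(1), "i")
  contigs <- contigs[keep_i]
  contigs[, v_pos := vapply(anno, `[[`, integer(1), "v_pos")]
  contigs[, j_end := vapply(anno, `[[`, integer(1), "j_end")]
  cdr3s <- lapply(anno, `[[`, "cdr3")

  # perfect paired-read confirmation (batched over all candidates)
  evidence <- unname(map_reads_batch(cand, setNames(contigs$seq, contigs$id),
                                     min_insert = cfg$min_insert,
                                     max_insert = cfg$max_insert))
  accepted <- filter_contigs(contigs, evidence, min_pairs = cfg$min_pairs,
                             min_depth = cfg$min_depth,
                             min_distinct_starts = cfg$min_distinct_starts,
                             max_start_gap = cfg$max_start_gap,
                             min_unique_pairs = cfg$min_unique_pairs,
                             min_contig_len = cfg$min_contig_len,
                             tail_extent = cfg$tail_extent)
  counts$contigs_accepted <- nrow(accepted)
  if (nrow(accepted) == 0L) return(empty_result(counts))
  evs <- attr(accepted, "evidence")
  pair_map <- attr(accepted, "pair_map")
  acc_cdr3 <- cdr3s[match(accepted$id, contigs$id)]
  # shift CDR3 coordinates into the trimmed contig frame
  acc_cdr3 <- Map(function(cd, off) {
    cd$nt_start <- cd$nt_start - off
    cd$nt_end <- cd$nt_end - off
    cd
  }, acc_cdr3, accepted$trim_offset)

  # postprocessing
  c_refs <- germline_seqs(db, "C")
  accepted[, cdr3_aa := vapply(acc_cdr3, `[[`, character(1), "aa_sequence")]
  accepted[, isotype := vapply(seq, assign_isotype, character(1),
                               constant_refs = c_refs,
                               tail_len = cfg$tail_len,
                               max_mm = cfg$isotype_max_mm)]
  vj <- Map(assign_vj, accepted$seq, acc_cdr3, MoreArgs = list(db = db))
  accepted[, v_gene := vapply(vj, `[[`, character(1), "v_gene")]
  accepted[, j_gene := vapply(vj, `[[`, character(1), "j_gene")]
  accepted[, v_identity := vapply(vj, `[[`, numeric(1), "v_identity")]
  ab <- quantify_em(pair_map, setNames(nchar(accepted$seq), accepted$id),
                    em_iters = cfg$em_iters, tol = cfg$em_tol)
  accepted[, abundance := ab[id]]
  clonotypes <- cluster_clonotypes(accepted)
  summary <- repertoire_summary(clonotypes)
  counts$clonotypes <- nrow(clonotypes)
  list(contigs = accepted[], clonotypes = clonotypes, summary = summary,
       mapped_pairs = evs, counts = counts)
}

write_outputs <- function(result, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(cfg$out_dir, "contigs.fasta")
  sam <- file.path(cfg$out_dir, "contigs.sam")
  cl <- file.path(cfg$out_dir, "clonotypes.tsv")
  sm <- file.path(cfg$out_dir, "summary.tsv")
  lg <- file.path(cfg$out_dir, "run_log.yaml")
  ct <- result$contigs
  if (nrow(ct) > 0L) write_fasta(setNames(ct$seq, ct$id), fa) else file.create(fa)
  write_contig_sam(result, sam)
  clono <- copy(result$clonotypes)
  if (nrow(clono) > 0L)
    clono[, members := vapply(members, paste, character(1), collapse = ",")]
  fwrite(clono, cl, sep = "\t")
  s <- result$summary
  fwrite(data.table(richness = s$richness, total_abundance = s$total_abundance,
                    evenness = s$evenness, group = s$group), sm, sep = "\t")
  cfg_echo <- result$config
  cfg_echo <- cfg_echo[!vapply(cfg_echo, is.null, logical(1))]
  yaml::write_yaml(list(config = cfg_echo,
                        counts = lapply(result$counts, as.list)), lg)
  c(contigs_fasta = fa, contigs_sam = sam, clonotypes_tsv = cl,
    summary_tsv = sm, run_log = lg)
}

#' Write mapped pairs as SAM against the accepted contigs
#'
#' Proper header (`@HD`, one `@SQ` per contig, `@PG`); perfect ungapped
#' pairs as `<len>M` records with FLAG/POS/TLEN set for a
#' forward/reverse-complement pair.
#'
#' @param result a `pipeline_result`.
#' @param path output SAM path.
#' @export
write_contig_sam <- function(result, path) {
  ct <- result$contigs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  if (nrow(ct) > 0L)
    writeLines(paste0("@SQ\tSN:", ct$id, "\tLN:", nchar(ct$seq)), con)
  writeLines("@PG\tID:igasm\tPN:igasm", con)
  evs <- result$mapped_pairs
  if (is.null(evs)) return(invisible(path))
  for (i in seq_along(evs)) {
    p <- evs[[i]]$pairs
    if (nrow(p) == 0L) next
    cseq <- ct$seq[i]
    fwd_seq <- substring(cseq, p$fwd_pos + 1L, p$fwd_pos + p$fwd_len)
    rev_seq <- substring(cseq, p$rev_pos + 1L, p$rev_pos + p$rev_len)
    writeLines(paste(p$name, 99L, ct$id[i], p$fwd_pos + 1L, 60L,
                     paste0(p$fwd_len, "M"), "=", p$rev_pos + 1L, p$insert,
                     fwd_seq, "*", sep = "\t"), con)
    writeLines(paste(p$name, 147L, ct$id[i], p$rev_pos + 1L, 60L,
                     paste0(p$rev_len, "M"), "=", p$fwd_pos + 1L, -p$insert,
                     rev_seq, "*", sep = "\t"), con)
  }
  invisible(path)
}
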