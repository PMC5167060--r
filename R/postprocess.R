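#' Assign an isotype from the contig tail
#'
#' The trailing `tail_len` bases of a contig (constant-region sequence) are
#' matched ungapped against every window of each constant-region reference;
#' the isotype of the best match is returned when it has at most `max_mm`
#' mismatches. Ties between distinct isotypes yield `"unknown"`.
#'
#' @param contig_seq contig DNA string (>= `tail_len`).
#' @param constant_refs named character vector of constant-region
#'   references; isotype class is the reference id stripped of
#'   subclass/allele suffix (e.g. `IGHG1*01` -> `IGHG`).
#' @param tail_len tail length (default 48).
#' @param max_mm maximum mismatches (default 4).
#' @return a single isotype string (e.g. `"IGHG"`) or `"unknown"`.
#' @export
assign_isotype <- function(contig_seq, constant_refs, tail_len = 48L,
                           max_mm = 4L) {
  if (length(constant_refs) == 0L || nchar(contig_seq) < tail_len)
    return("unknown")
  tail_seq <- substr(contig_seq, nchar(contig_seq) - tail_len + 1L,
                     nchar(contig_seq))
  res <- .best_window_mismatch(unname(constant_refs), tail_seq, stop_at = 0L)
  mm <- res$mismatches
  mm[is.na(mm)] <- tail_len + 1L
  best <- min(mm)
  if (best > max_mm) return("unknown")
  iso <- isotype_class(names(constant_refs)[mm == best])
  if (length(unique(iso)) > 1L) return("unknown")
  iso[1]
}

# IGHG1*01 -> IGHG ; IGKC*01 -> IGKC
isotype_class <- function(ids) sub("([0-9]*)(\\*.*)?$", "", ids)

#' Assign V and J genes and V-region identity
#'
#' The contig region upstream of the CDR3 is locally aligned (match +1,
#' mismatch -1, gap -4) against every germline V of the chain, and the
#' region downstream against every germline J; the best-scoring segments
#' win (ties broken by lexicographically smallest id, flagged). V identity
#' is matches over aligned columns of the best V alignment, a proxy for
#' somatic-hypermutation load.
#'
#' @param contig_seq contig DNA string.
#' @param cdr3 a CDR3 call from [locate_cdr3()].
#' @param db a `germline_db`.
#' @return list(`v_gene`, `j_gene`, `v_identity`, `tied`).
#' @export
assign_vj <- function(contig_seq, cdr3, db) {
  v_refs <- germline_seqs(db, "V")
  j_refs <- germline_seqs(db, "J")
  up <- substr(contig_seq, 1L, cdr3$nt_end + 1L)
  down <- substr(contig_seq, cdr3$nt_start + 1L, nchar(contig_seq))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  best_of <- function(region, refs) {
    if (length(refs) == 0L) return(list(id = NA_character_, identity = NA_real_,
                                        tied = FALSE))
    alns <- lapply(refs, function(r)
      Biostrings::pairwiseAlignment(region, r, type = "local",
                                    substitutionMatrix = mat,
                                    gapOpening = 0, gapExtension = 4))
    scores <- vapply(alns, Biostrings::score, numeric(1))
    top <- which(scores == max(scores))
    tied <- length(top) > 1L
    pick <- top[order(names(refs)[top])][1]
    a <- alns[[pick]]
    ident <- Biostrings::nmatch(a) / Biostrings::nchar(a)
    list(id = names(refs)[pick], identity = ident, tied = tied)
  }
  v <- best_of(up, v_refs)
  j <- best_of(down, j_refs)
  list(v_gene = v$id, j_gene = j$id, v_identity = v$identity,
       tied = v$tied || j$tied)
}

#' Quantify contig abundance by expectation-maximization
#'
#' Pairs mapping to a single contig contribute one full fragment to it;
#' pairs mapping to several contigs are fractionally assigned by an EM loop
#' over length-normalized contig relative abundances. The sum of abundances
#' equals the number of mapped pairs.
#'
#' @param pair_map data.table with columns `name` (pair id) and `contig_id`
#'   (each row: this pair maps to this contig).
#' @param contig_lens named integer vector of contig lengths.
#' @param em_iters maximum iterations (default 200).
#' @param tol convergence tolerance on max absolute abundance change
#'   (default 1e-6).
#' @return named numeric vector of expected fragment counts per contig.
#' @export
quantify_em <- function(pair_map, contig_lens, em_iters = 200L, tol = 1e-6) {
  ab <- setNames(rep(0, length(contig_lens)), names(contig_lens))
  if (is.null(pair_map) || nrow(pair_map) == 0L) return(ab)
  pm <- unique(as.data.table(pair_map)[, .(name, contig_id)])
  pm <- pm[contig_id %chin% names(contig_lens)]
  if (nrow(pm) == 0L) return(ab)
  n_pairs <- uniqueN(pm$name)
  cid <- names(contig_lens)
  eff <- pmax(contig_lens, 1L)
  pm[, x := match(contig_id, cid)]
  gid <- match(pm$name, unique(pm$name))
  xi <- pm$x
  theta <- rep(1 / length(cid), length(cid))
  frac_counts <- function(theta) {
    w <- theta[xi] / eff[xi]
    tot <- rowsum(w, gid)
    p <- w / tot[gid, 1L]
    rowsum_x <- rowsum(p, xi)
    counts <- numeric(length(cid))
    counts[as.integer(rownames(rowsum_x))] <- rowsum_x[, 1L]
    counts
  }
  for (it in seq_len(em_iters)) {
    counts <- frac_counts(theta)
    new_theta <- counts / n_pairs
    if (max(abs(new_theta - theta)) < tol) { theta <- new_theta; break }
    theta <- new_theta
  }
  setNames(frac_counts(theta), cid)
}

#' Cluster contigs into clonotypes
#'
#' Contigs sharing an identical CDR3 amino-acid sequence, V gene, J gene
#' and isotype form one clonotype; clonotype abundance is the sum of member
#' abundances.
#'
#' @param annotated data.table with columns `id`, `cdr3_aa`, `v_gene`,
#'   `j_gene`, `isotype`, `abundance`.
#' @return data.table of clonotypes: `clonotype_id`, `cdr3_aa`, `v_gene`,
#'   `j_gene`, `isotype`, `abundance`, `n_contigs`, `members` (list).
#' @export
cluster_clonotypes <- function(annotated) {
  a <- as.data.table(annotated)
  if (nrow(a) == 0L)
    return(data.table(clonotype_id = character(0), cdr3_aa = character(0),
                      v_gene = character(0), j_gene = character(0),
                      isotype = character(0), abundance = numeric(0),
                      n_contigs = integer(0), members = list()))
  cl <- a[, .(abundance = sum(abundance), n_contigs = .N, members = list(id)),
          by = .(cdr3_aa, v_gene, j_gene, isotype)]
  setorder(cl, -abundance)
  cl[, clonotype_id := sprintf("clone%04d", seq_len(.N))]
  data.table::setcolorder(cl, c("clonotype_id", "cdr3_aa", "v_gene", "j_gene",
                                "isotype", "abundance", "n_contigs", "members"))
  cl[]
}

#' Pielou evenness of a repertoire
#'
#' Shannon entropy of the clonotype proportions divided by the natural log
#' of the number of clonotypes. Zero abundances are dropped; a single
#' clonotype has evenness 0 by convention.
#'
#' @param abundances numeric vector of clonotype abundances.
#' @return evenness in \[0, 1\].
#' @export
pielou_evenness <- function(abundances) {
  a <- abundances[!is.na(abundances) & abundances > 0]
  if (length(a) == 0L) stop("need at least one positive abundance")
  s <- length(a)
  if (s == 1L) return(0)
  p <- a / sum(a)
  h <- -sum(p * log(p))
  h / log(s)
}

#' Stratify a sample by BCR abundance and evenness
#'
#' @param total_abundance summed clonotype abundance.
#' @param evenness Pielou evenness in \[0, 1\].
#' @param abundance_cut high/low abundance threshold (default 1000; low is
#'   `<=` the cut).
#' @param evenness_cut high/low evenness threshold (default 0.8; low is
#'   `<=` the cut).
#' @return one of `"low_abundance"`, `"high_abundance_high_evenness"`,
#'   `"high_abundance_low_evenness"`.
#' @export
stratify_sample <- function(total_abundance, evenness, abundance_cut = 1000,
                            evenness_cut = 0.8) {
  stopifnot(evenness >= 0, evenness <= 1)
  if (total_abundance <= abundance_cut) return("low_abundance")
  if (evenness > evenness_cut) return("high_abundance_high_evenness")
  "high_abundance_low_evenness"
}

#' Summarise a repertoire
#'
#' @param clonotypes data.table from [cluster_clonotypes()].
#' @return list with `richness`, `total_abundance`, `evenness`, `group`,
#'   `cdr3_lengths` (amino-acid lengths).
#' @export
repertoire_summary <- function(clonotypes) {
  if (nrow(clonotypes) == 0L)
    return(list(richness = 0L, total_abundance = 0, evenness = NA_real_,
                group = "low_abundance", cdr3_lengths = integer(0)))
  total <- sum(clonotypes$abundance)
  ev <- pielou_evenness(clonotypes$abundance)
  list(richness = nrow(clonotypes), total_abundance = total, evenness = ev,
       group = stratify_sample(total, ev),
       cdr3_lengths = nchar(clonotypes$cdr3_aa))
}
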