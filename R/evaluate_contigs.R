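#' Find V/J anchor hits on a contig
#'
#' Ungapped Hamming scan of every anchor against the forward strand of the
#' contig; hits with at most `max_mm` mismatches are reported. The best V
#' hit is the lowest-mismatch, leftmost hit; the best J hit is the
#' lowest-mismatch, rightmost hit.
#'
#' @param contig_seq contig DNA string (length >= anchor length).
#' @param anchors an `anchor_set` from [extract_anchors()].
#' @param max_mm maximum mismatches (default 4).
#' @return data.table of hits: `anchor_class`, `anchor`, `segments` (list),
#'   `pos` (0-based), `mismatches`, `offset` (anchor offset from the segment
#'   terminus), plus attribute `best` = list(v = row, j = row) or NULL.
#' @export
find_anchor_hits <- function(contig_seq, anchors, max_mm = 4L) {
  scan_side <- function(tab, cls) {
    if (nrow(tab) == 0L) return(NULL)
    res <- lapply(seq_len(nrow(tab)), function(i) {
      mm <- .hamming_scan(contig_seq, tab$anchor[i])
      hit <- which(mm <= max_mm)
      if (length(hit) == 0L) return(NULL)
      data.table(anchor_class = cls, anchor = tab$anchor[i],
                 segments = rep(tab$segments[i], length(hit)),
                 pos = hit - 1L, mismatches = mm[hit],
                 offset = tab$offset[i])
    })
    rbindlist(res[!vapply(res, is.null, logical(1))])
  }
  hits <- rbindlist(list(scan_side(anchors$v_anchors, "V"),
                         scan_side(anchors$j_anchors, "J")))
  if (nrow(hits) == 0L)
    hits <- data.table(anchor_class = character(0), anchor = character(0),
                       segments = list(), pos = integer(0),
                       mismatches = integer(0), offset = integer(0))
  v <- hits[anchor_class == "V"][order(mismatches, pos)]
  j <- hits[anchor_class == "J"][order(mismatches, -pos)]
  best <- NULL
  if (nrow(v) > 0L && nrow(j) > 0L)
    best <- list(v = v[1], j = j[1])
  data.table::setattr(hits, "best", best)
  hits
}

#' Locate the CDR3 on a contig
#'
#' The reading frame is fixed by the V anchor hit position and the germline
#' V frame offset. The call scans for an in-frame conserved cysteine codon
#' (TGT/TGC) at or just after the V anchor region and an in-frame conserved
#' tryptophan (TGG, IGH) or phenylalanine (TTT/TTC, IGK/IGL) codon inside
#' the J anchor region, and accepts the innermost pair (rightmost Cys,
#' leftmost Trp/Phe) whose amino-acid span falls within `aa_window` and
#' contains no stop codon.
#'
#' @param contig_seq contig DNA string.
#' @param v_hit,j_hit single-row data.tables (best hits from
#'   [find_anchor_hits()]).
#' @param chain "IGH", "IGK" or "IGL".
#' @param v_frame_offset frame offset of the V segment behind `v_hit`.
#' @param v_seg_len length of that germline V segment.
#' @param aa_window allowed CDR3 amino-acid length range (default IGH
#'   c(5, 38); use c(4, 20) for light chains).
#' @param max_gap maximum V-anchor-end to J-anchor-start distance
#'   (default 150 nt).
#' @param anchor_len anchor length (default 16).
#' @return list(`nt_start`, `nt_end` (0-based inclusive), `nt_sequence`,
#'   `aa_sequence`) or NULL.
#' @export
locate_cdr3 <- function(contig_seq, v_hit, j_hit, chain = "IGH",
                        v_frame_offset = 0L, v_seg_len = NULL,
                        aa_window = c(5L, 38L), max_gap = 150L,
                        anchor_len = 16L) {
  if (is.null(v_hit) || is.null(j_hit)) return(NULL)
  v_pos <- v_hit$pos
  j_pos <- j_hit$pos
  if (v_pos >= j_pos) return(NULL)
  if (j_pos - (v_pos + anchor_len) > max_gap) return(NULL)
  if (is.null(v_seg_len)) stop("v_seg_len required to fix the reading frame")
  # segment coordinate of the anchor start (0-based)
  a_seg_start <- v_seg_len - v_hit$offset - anchor_len
  # contig positions p in codon-start phase satisfy
  # (p - v_pos + a_seg_start - v_frame_offset) %% 3 == 0
  phase_ok <- function(p) (p - v_pos + a_seg_start - v_frame_offset) %% 3L == 0L
  n <- nchar(contig_seq)
  c_window <- seq(v_pos, min(v_pos + anchor_len + 9L, n - 3L))
  c_starts <- c_window[phase_ok(c_window)]
  c_codons <- substring(contig_seq, c_starts + 1L, c_starts + 3L)
  c_starts <- c_starts[c_codons %chin% c("TGT", "TGC")]
  if (length(c_starts) == 0L) return(NULL)
  w_codons_ok <- if (chain == "IGH") "TGG" else c("TTT", "TTC")
  w_window <- seq(max(j_pos - 9L, 0L), min(j_pos + anchor_len - 3L, n - 3L))
  w_starts <- w_window[phase_ok(w_window)]
  w_codons <- substring(contig_seq, w_starts + 1L, w_starts + 3L)
  w_starts <- w_starts[w_codons %chin% w_codons_ok]
  if (length(w_starts) == 0L) return(NULL)
  # innermost pair first: rightmost Cys, then leftmost Trp/Phe after it
  for (cs in rev(c_starts)) {
    for (ws in w_starts) {
      if (ws <= cs) next
      nt_len <- ws + 3L - cs
      if (nt_len %% 3L != 0L) next      # guaranteed by shared phase
      aa_len <- nt_len %/% 3L
      if (aa_len < aa_window[1] || aa_len > aa_window[2]) next
      nt <- substr(contig_seq, cs + 1L, ws + 3L)
      aa <- translate_dna(nt)
      if (grepl("\\*", aa)) next        # stop codon: reject this pairing
      return(list(nt_start = cs, nt_end = ws + 2L, nt_sequence = nt,
                  aa_sequence = aa))
    }
  }
  NULL
}

#' Map reads to a contig by perfect matching
#'
#' All extracted reads are hashed and the contig is scanned window by
#' window for perfect (exact substring) matches on either strand. A pair is
#' mapped iff both mates match exactly, in opposite orientations with the
#' forward mate upstream, and the outer insert span lies within
#' `[min_insert, max_insert]`.
#'
#' @param reads a `read_set` (columns `name`, `read_index`, `seq`).
#' @param contig_seq contig DNA string.
#' @param min_insert,max_insert allowed outer insert span (defaults 50 and
#'   1000).
#' @return list with `pairs` (data.table `name`, `fwd_mate`, `fwd_pos`,
#'   `rev_pos` 0-based, `insert`), `depth` (integer vector, one per contig
#'   base), `n_pairs`, `distinct_starts`.
#' @export
map_reads_perfect <- function(reads, contig_seq, min_insert = 50L,
                              max_insert = 1000L) {
  map_reads_batch(reads, c(contig = contig_seq), min_insert, max_insert)[[1]]
}

# vectorized core: perfect-match pair mapping of one read set against many
# contigs at once; returns a named list of evidence objects
map_reads_batch <- function(reads, contig_seqs, min_insert = 50L,
                            max_insert = 1000L) {
  rs <- as.data.table(reads)
  cl <- nchar(contig_seqs)
  cids <- names(contig_seqs)
  empty <- function(L) list(
    pairs = data.table(name = character(0), fwd_mate = integer(0),
                       fwd_pos = integer(0), rev_pos = integer(0),
                       fwd_len = integer(0), rev_len = integer(0),
                       insert = integer(0)),
    depth = integer(L), n_pairs = 0L, distinct_starts = 0L)
  out <- setNames(lapply(cl, empty), cids)
  if (nrow(rs) == 0L || length(contig_seqs) == 0L) return(out)
  rlen <- nchar(rs$seq)
  windows <- rbindlist(lapply(sort(unique(rlen)), function(len) {
    use <- cl >= len
    if (!any(use)) return(NULL)
    nw <- cl[use] - len + 1L
    ci <- rep(cids[use], nw)
    start <- unlist(lapply(nw, seq_len), use.names = FALSE)
    data.table(contig_id = ci,
               win = substring(contig_seqs[ci], start, start + len - 1L),
               pos = start - 1L, len = len)
  }))
  lookup <- function(seqs, orient) {
    q <- data.table(win = seqs, row = seq_along(seqs), qlen = nchar(seqs))
    j <- windows[q, on = c("win", len = "qlen"), allow.cartesian = TRUE,
                 nomatch = NULL]
    if (nrow(j) == 0L) return(NULL)
    data.table(contig_id = j$contig_id, name = rs$name[j$row],
               read_index = rs$read_index[j$row], pos = j$pos,
               orient = orient, len = j$len)
  }
  matches <- rbindlist(list(lookup(rs$seq, "F"), lookup(revcomp(rs$seq), "R")))
  if (is.null(matches) || nrow(matches) == 0L) return(out)
  m1 <- matches[read_index == 1L]
  m2 <- matches[read_index == 2L]
  pr <- merge(m1, m2, by = c("contig_id", "name"), allow.cartesian = TRUE,
              suffixes = c("_1", "_2"))
  if (nrow(pr) == 0L) return(out)
  # opposite orientations, forward mate upstream
  ok_fr <- pr$orient_1 == "F" & pr$orient_2 == "R" & pr$pos_1 <= pr$pos_2
  ok_rf <- pr$orient_1 == "R" & pr$orient_2 == "F" & pr$pos_2 <= pr$pos_1
  pr <- pr[ok_fr | ok_rf]
  if (nrow(pr) == 0L) return(out)
  fwd_first <- pr$orient_1 == "F"
  pairs <- data.table(
    contig_id = pr$contig_id,
    name = pr$name,
    fwd_mate = ifelse(fwd_first, 1L, 2L),
    fwd_pos = ifelse(fwd_first, pr$pos_1, pr$pos_2),
    rev_pos = ifelse(fwd_first, pr$pos_2, pr$pos_1),
    fwd_len = ifelse(fwd_first, pr$len_1, pr$len_2),
    rev_len = ifelse(fwd_first, pr$len_2, pr$len_1)
  )
  pairs[, insert := rev_pos + rev_len - fwd_pos]
  pairs <- pairs[insert >= min_insert & insert <= max_insert]
  # a physical pair counts once per contig even if it matches at
  # several offsets
  setorder(pairs, contig_id, name, fwd_pos, rev_pos)
  pairs <- pairs[!duplicated(pairs[, .(contig_id, name)])]
  for (split_p in split(pairs, by = "contig_id")) {
    cid <- split_p$contig_id[1]
    L <- cl[[cid]]
    covs <- IRanges::coverage(
      IRanges::IRanges(start = c(split_p$fwd_pos, split_p$rev_pos) + 1L,
                       width = c(split_p$fwd_len, split_p$rev_len)),
      width = L)
    out[[cid]] <- list(
      pairs = split_p[, .(name, fwd_mate, fwd_pos, rev_pos, fwd_len,
                          rev_len, insert)],
      depth = as.integer(covs), n_pairs = nrow(split_p),
      distinct_starts = uniqueN(c(split_p$fwd_pos, split_p$rev_pos)))
  }
  out
}

#' Filter candidate contigs on read evidence
#'
#' Each candidate is first trimmed to its read-confirmed span: the head is
#' cut to the first position whose mapped-pair footprint depth reaches
#' `min_depth` (the first ~k bases of a path are spelled by k-mers whose
#' supporting reads overhang the contig start and can never be mapped back,
#' so they carry no pair-level confirmation), and the tail is cut to the
#' last position reached by a junction-anchored pair (a pair whose fragment
#' overlaps the V-anchor..J-anchor span). A trimmed candidate is then
#' accepted when (1) it retains at least `min_pairs` mapped pairs, (2)
#' every base of the trimmed span is covered to `min_depth`, with at least
#' `min_distinct_starts` distinct mate start positions, (3) the largest gap
#' between consecutive distinct mate start positions (sentinel at the last
#' startable offset) is at most `max_start_gap`, and (4) after exact and
#' substring/reverse-complement containment dedup, iterative peeling on
#' cross-contig unique support: the weakest candidate (fewest pairs mapping
#' to it alone, ties by fewest total pairs, then lowest path score) is
#' removed and uniqueness recomputed, until every survivor retains at least
#' `min_unique_pairs` pairs mapping to no other survivor.
#'
#' Trimming plus peeling rejects the failure modes of exhaustive braid
#' traversal: paths whose head or tail content is k-mer-supported but not
#' pair-confirmed (including isotype-swapped tails that ride on other
#' clones\' constant-region reads), and mosaic paths braiding hypermutated
#' clones that share a germline V, whose support is a subset of their
#' parents\' support. `min_unique_pairs` sits above 2 because a recurrent
#' sequencing error observed in two distinct reads survives graph pruning
#' and yields a one-substitution variant carrying exactly two unique pairs.
#'
#' @param contigs data.table from [traverse()] with anchor columns attached
#'   (`v_pos`, `j_end`, both 0-based).
#' @param evidence list of [map_reads_perfect()] results, one per contig row.
#' @param min_pairs,min_depth,min_distinct_starts,max_start_gap,min_unique_pairs
#'   thresholds (defaults 10, 2, 5, 25, 3).
#' @param min_contig_len minimum retained length after trimming (default
#'   250).
#' @return the accepted subset of `contigs` (sequences trimmed; columns
#'   `trim_offset`, `n_pairs`, `unique_pairs` added; `v_pos`/`j_end`
#'   shifted to trimmed coordinates) with attributes `evidence` (trimmed,
#'   per accepted contig) and `pair_map` (pair-to-contig incidence used by
#'   the quantifier).
#' @export
filter_contigs <- function(contigs, evidence, min_pairs = 10L, min_depth = 2L,
                           min_distinct_starts = 5L, max_start_gap = 25L,
                           min_unique_pairs = 3L, min_contig_len = 250L,
                           tail_extent = 80L) {
  stopifnot(nrow(contigs) == length(evidence))
  if (nrow(contigs) == 0L) return(contigs)
  contigs <- copy(contigs)
  contigs[, trim_offset := 0L]
  ok <- logical(nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    ev <- evidence[[i]]
    if (ev$n_pairs < min_pairs) next
    p <- ev$pairs
    L <- nchar(contigs$seq[i])
    v_pos <- contigs$v_pos[i]
    j_end <- contigs$j_end[i]
    rev_end <- p$rev_pos + p$rev_len - 1L
    # a pair vouches for the tail only when it starts at or before the V
    # anchor, i.e. its fragment overlaps clone-specific junction content;
    # shared J/constant-region pairs from other clones do not qualify
    anchored <- p$fwd_pos <= v_pos & rev_end >= v_pos
    if (!any(anchored)) next
    lo_cand <- min(p$fwd_pos[anchored])
    hi_cand <- max(rev_end[anchored])
    dep <- ev$depth
    deep <- which(dep >= min_depth) - 1L        # 0-based positions
    lo_ok <- deep[deep >= lo_cand]
    hi_ok <- deep[deep <= hi_cand]
    if (length(lo_ok) == 0L || length(hi_ok) == 0L) next
    lo <- lo_ok[1]
    hi <- hi_ok[length(hi_ok)]
    # cap the tail at a fixed distance past the J anchor so that all
    # accepted contigs cover a comparable stretch of the shared constant
    # region; otherwise the deepest-reaching contig soaks up every
    # clone's constant-region fragments during quantification
    hi <- min(hi, j_end + tail_extent)
    if (lo > v_pos || hi < j_end) next          # anchors must be confirmed
    # depth is re-derived from the pairs the span retains (a pair lost to
    # the trim no longer attests the boundary bases), and the span shrinks
    # to the maximal sufficiently-covered run through the anchors
    L <- nchar(contigs$seq[i])
    keep_p <- p$fwd_pos >= lo & (p$rev_pos + p$rev_len - 1L) <= hi
    p <- p[keep_p]
    if (nrow(p) < min_pairs) next
    dep <- as.integer(IRanges::coverage(
      IRanges::IRanges(start = c(p$fwd_pos, p$rev_pos) + 1L,
                       width = c(p$fwd_len, p$rev_len)), width = L))
    ok_pos <- dep >= min_depth
    if (!all(ok_pos[(v_pos + 1L):(j_end + 1L)])) next
    runs <- rle(ok_pos)
    run_end <- cumsum(runs$lengths)
    run_start <- run_end - runs$lengths + 1L
    ri <- which(runs$values & run_start <= v_pos + 1L & run_end >= v_pos + 1L)
    lo <- max(lo, run_start[ri] - 1L)
    hi <- min(hi, run_end[ri] - 1L)
    if (hi < j_end) next
    if (hi - lo + 1L < min_contig_len) next
    keep_p <- p$fwd_pos >= lo & (p$rev_pos + p$rev_len - 1L) <= hi
    p <- p[keep_p]
    if (nrow(p) < min_pairs) next
    starts <- sort(unique(c(p$fwd_pos, p$rev_pos)))
    if (length(starts) < min_distinct_starts) next
    rl <- min(p$fwd_len, p$rev_len)
    gaps <- diff(c(starts, hi - rl + 1L))
    if (length(gaps) > 0L && max(gaps) > max_start_gap) next
    # commit the trim
    p[, fwd_pos := fwd_pos - lo]
    p[, rev_pos := rev_pos - lo]
    newlen <- hi - lo + 1L
    covs <- IRanges::coverage(
      IRanges::IRanges(start = c(p$fwd_pos, p$rev_pos) + 1L,
                       width = c(p$fwd_len, p$rev_len)), width = newlen)
    evidence[[i]] <- list(pairs = p, depth = as.integer(covs),
                          n_pairs = nrow(p),
                          distinct_starts = length(starts))
    data.table::set(contigs, i, "seq",
                    substr(contigs$seq[i], lo + 1L, hi + 1L))
    data.table::set(contigs, i, "v_pos", v_pos - lo)
    data.table::set(contigs, i, "j_end", j_end - lo)
    data.table::set(contigs, i, "trim_offset", lo)
    ok[i] <- TRUE
  }
  out <- contigs[ok]
  evs <- evidence[ok]
  if (nrow(out) == 0L) return(out)
  # containment dedup: drop contigs equal to or contained in another
  # (either strand); the longer representative keeps its own evidence
  keep <- rep(TRUE, nrow(out))
  rc <- revcomp(out$seq)
  nlen <- nchar(out$seq)
  ord <- order(-nlen, out$seq)
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (!keep[i]) next
    for (b in seq_along(ord)) {
      j <- ord[b]
      if (i == j || !keep[j]) next
      if (nlen[j] > nlen[i]) next
      if (nlen[j] == nlen[i] && b < a) next
      if (grepl(out$seq[j], out$seq[i], fixed = TRUE) ||
          grepl(rc[j], out$seq[i], fixed = TRUE))
        keep[j] <- FALSE
    }
  }
  out <- out[keep]
  evs <- evs[keep]
  out[, n_pairs := vapply(evs, `[[`, integer(1), "n_pairs")]
  # iterative peeling on cross-contig unique pair support; a pair counts
  # toward a candidate's unique support only when it maps in the contig
  # interior (a read length away from either trimmed end), because
  # candidates trimmed to slightly different spans otherwise acquire
  # spurious margin-only unique pairs
  pair_map <- rbindlist(lapply(seq_along(evs), function(i) {
    p <- evs[[i]]$pairs
    if (nrow(p) == 0L) return(NULL)
    # margins exceed the trim-position scatter between near-identical
    # candidates (head) and the anchored-reach scatter (tail), so that a
    # pair can only be credited as unique for reasons of content, not of
    # span bookkeeping
    len <- nchar(out$seq[i])
    data.table(contig_id = out$id[i], name = p$name,
               interior = p$fwd_pos >= 16L &
                 (p$rev_pos + p$rev_len) <= (len - 50L))
  }))
  # integer-indexed incidence with incremental owner-count updates
  pm <- copy(pair_map)
  pm[, ci := match(contig_id, out$id)]
  pnames <- unique(pm$name)
  pm[, pi := match(name, pnames)]
  setorder(pm, pi)
  np_pairs <- length(pnames)
  pair_start <- c(0L, cumsum(tabulate(pm$pi, nbins = np_pairs)))
  cand_rows <- split(seq_len(nrow(pm)), pm$ci)
  alive <- rep(TRUE, nrow(out))
  nc <- tabulate(pm$pi, nbins = np_pairs)     # alive candidates per pair
  uniq <- integer(nrow(out))
  one <- which(nc == 1L)
  if (length(one) > 0L) {
    rows1 <- pair_start[one] + 1L
    tab <- tabulate(pm$ci[rows1][pm$interior[rows1]], nbins = nrow(out))
    uniq <- uniq + tab
  }
  lens <- setNames(nchar(out$seq), out$id)
  n_pairs_v <- out$n_pairs
  score_v <- out$path_score
  em_mass <- rep(0, nrow(out))
  em_stale <- Inf                 # refresh the EM mass estimates on entry
  repeat {
    idx <- which(alive)
    if (length(idx) == 0L) break
    failing <- idx[uniq[idx] < min_unique_pairs]
    if (length(failing) == 0L) break
    # among candidates lacking unique support, discard the one carrying
    # the least expected fragment mass under the shared EM allocation:
    # mosaic paths live off windows shared with the clones they braid and
    # attract little mass, so parents outlive their hybrids
    if (em_stale >= 25L) {
      sub <- pm[alive[ci] == TRUE]
      ab <- quantify_em(sub[, .(name, contig_id)], lens[idx],
                        em_iters = 50L, tol = 1e-3)
      em_mass[] <- 0
      em_mass[match(names(ab), out$id)] <- ab
      em_stale <- 0L
    }
    ord <- order(em_mass[failing], n_pairs_v[failing], score_v[failing],
                 out$id[failing])
    victim <- failing[ord[1]]
    alive[victim] <- FALSE
    em_stale <- em_stale + 1L
    for (r in cand_rows[[as.character(victim)]]) {
      p <- pm$pi[r]
      nc[p] <- nc[p] - 1L
      if (nc[p] == 1L) {
        rows <- (pair_start[p] + 1L):pair_start[p + 1L]
        owner <- rows[alive[pm$ci[rows]]]
        if (length(owner) == 1L && pm$interior[owner])
          uniq[pm$ci[owner]] <- uniq[pm$ci[owner]] + 1L
      }
    }
  }
  out[, unique_pairs := uniq]
  out <- out[alive]
  evs <- evs[alive]
  data.table::setattr(out, "evidence", evs)
  data.table::setattr(out, "pair_map",
                      pair_map[contig_id %chin% out$id, .(name, contig_id)])
  out
}
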