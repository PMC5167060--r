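#' Find candidate source nodes
#'
#' Source vertices are condensed nodes with zero incoming edges.
#'
#' @param g a `condensed_graph`.
#' @return character vector of node ids.
#' @export
find_sources <- function(g) {
  g$nodes$id[!g$nodes$id %chin% unique(g$edges$to)]
}

#' Score a sequence for germline V homology
#'
#' A hash-table seed stage (exact shared `seed_len`-mer) gates a local
#' (Smith-Waterman) alignment with match +1, mismatch -1 and linear gap -4
#' against each seeded V segment. The best-scoring segment is returned when
#' its score reaches `min_score`.
#'
#' @param seq DNA string to score.
#' @param v_segments named character vector of germline V sequences.
#' @param seed_len seed length for the hash lookup (default 12).
#' @param min_score minimum accepted alignment score (default 23).
#' @param match,mismatch,gap alignment scoring parameters.
#' @return list(`segment`, `score`) or NULL when no seed or no segment
#'   reaches `min_score`.
#' @export
score_v_homology <- function(seq, v_segments, seed_len = 12L, min_score = 23L,
                             match = 1L, mismatch = -1L, gap = 4L) {
  if (nchar(seq) < seed_len) return(NULL)
  seeded <- names(v_segments)[vapply(v_segments, function(v) {
    any(kmers_of(seq, seed_len) %chin% kmers_of(v, seed_len))
  }, logical(1))]
  if (length(seeded) == 0L) return(NULL)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  scores <- vapply(seeded, function(sid) {
    Biostrings::pairwiseAlignment(seq, v_segments[[sid]], type = "local",
                                  substitutionMatrix = mat, gapOpening = 0,
                                  gapExtension = gap, scoreOnly = TRUE)
  }, numeric(1))
  best <- which.max(scores)
  if (scores[best] < min_score) return(NULL)
  list(segment = seeded[best], score = unname(scores[best]))
}

# V-homology gate over all source nodes; returns accepted data.table
screen_sources <- function(g, v_segments, seed_len = 12L, min_score = 23L) {
  src <- find_sources(g)
  if (length(src) == 0L)
    return(data.table(node = character(0), segment = character(0),
                      score = numeric(0)))
  seqs <- setNames(g$nodes$seq, g$nodes$id)[src]
  hits <- lapply(seqs, score_v_homology, v_segments = v_segments,
                 seed_len = seed_len, min_score = min_score)
  ok <- !vapply(hits, is.null, logical(1))
  data.table(node = src[ok],
             segment = vapply(hits[ok], `[[`, character(1), "segment"),
             score = vapply(hits[ok], `[[`, numeric(1), "score"))
}

#' Traverse the condensed graph from accepted sources
#'
#' Depth-first enumeration. At each branch the child path score is the
#' current score times the edge ratio (edge frequency over the summed
#' frequency of all outgoing edges; a single outgoing edge has ratio one).
#' A path is emitted as a contig when it reaches a sink or the maximum
#' contig length (flagged `truncated`), provided it is at least
#' `min_contig_len` long; paths whose score drops below `min_path_score`
#' are abandoned. Children are visited in order of decreasing edge ratio,
#' ties by node id, for deterministic output.
#'
#' @param g a `condensed_graph`.
#' @param sources data.table from [screen_sources()] (or a character vector
#'   of node ids).
#' @param min_path_score abandon threshold in (0, 1] (default 0.001).
#' @param max_contig_len maximum contig length (default 360).
#' @param min_contig_len minimum emitted length (default 250).
#' @param max_paths_per_source traversal budget (default 10000 emissions).
#' @param max_node_visits times one node may recur within a path (default 2).
#' @return a data.table of contigs: `id`, `seq`, `path_score`, `source`,
#'   `truncated`, `nodes` (list of node ids).
#' @export
traverse <- function(g, sources, min_path_score = 0.001, max_contig_len = 360L,
                     min_contig_len = 250L, max_paths_per_source = 10000L,
                     max_node_visits = 2L) {
  stopifnot(min_path_score > 0, min_path_score <= 1,
            min_contig_len <= max_contig_len)
  src_ids <- if (is.character(sources)) sources else sources$node
  node_seq <- setNames(g$nodes$seq, g$nodes$id)
  adj <- split(g$edges[, .(to, freq)], g$edges$from)
  out <- list()
  ct <- 0L
  for (s in src_ids) {
    emitted <- 0L
    # stack of states: node, score, seq, path(list of node ids)
    stack <- list(list(node = s, score = 1.0, seq = node_seq[[s]], path = s))
    while (length(stack) > 0L) {
      st <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (emitted >= max_paths_per_source) {
        warning("traversal budget exhausted for source ", s)
        break
      }
      seqlen <- nchar(st$seq)
      if (seqlen >= max_contig_len) {
        ct <- ct + 1L
        out[[ct]] <- list(id = sprintf("c%05d", ct),
                          seq = substr(st$seq, 1L, max_contig_len),
                          path_score = st$score, source = s, truncated = TRUE,
                          nodes = list(st$path))
        emitted <- emitted + 1L
        next
      }
      ch <- adj[[st$node]]
      total <- if (is.null(ch)) 0L else sum(ch$freq)
      if (!is.null(ch) && nrow(ch) > 0L) {
        # edge ratios are defined over ALL outgoing edges, before the
        # revisit limit masks any child
        cnt <- vapply(ch$to, function(n) sum(st$path == n), integer(1))
        ch <- ch[cnt < max_node_visits]
      }
      if (is.null(ch) || nrow(ch) == 0L) {       # sink (or revisit-blocked)
        if (seqlen >= min_contig_len) {
          ct <- ct + 1L
          out[[ct]] <- list(id = sprintf("c%05d", ct), seq = st$seq,
                            path_score = st$score, source = s,
                            truncated = FALSE, nodes = list(st$path))
          emitted <- emitted + 1L
        }
        next
      }
      ratio <- ch$freq / total
      ord <- order(-ratio, ch$to)
      # push in reverse so the highest-ratio child is explored first
      for (i in rev(ord)) {
        sc <- st$score * ratio[i]
        if (sc < min_path_score) next
        nid <- ch$to[i]
        stack[[length(stack) + 1L]] <- list(
          node = nid, score = sc,
          seq = paste0(st$seq, substring(node_seq[[nid]], g$k)),
          path = c(st$path, nid))
      }
    }
  }
  if (ct == 0L)
    return(data.table(id = character(0), seq = character(0),
                      path_score = numeric(0), source = character(0),
                      truncated = logical(0), nodes = list()))
  rbindlist(out)
}
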