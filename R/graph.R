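#' Build the quality-aware de Bruijn graph
#'
#' Every read is inserted in both its stored orientation and its reverse
#' complement (unstranded RNA-seq). Each vertex is a k-mer carrying its total
#' observation count, the number of distinct supporting reads, and the sum of
#' Phred base qualities at each of its k positions; each edge is an observed
#' (k+1)-mer with its observation frequency.
#'
#' @param reads a `read_set` (columns `seq`, `qual`) or a character vector of
#'   sequences (then `quals` must be given or defaults to uniform Phred 35).
#' @param k k-mer size.
#' @param quals optional Phred+33 quality strings when `reads` is a character
#'   vector.
#' @param both_strands insert reverse complements too (default TRUE).
#' @return a `kmer_graph`: list with `k`, `vertices` (data.table `kmer`,
#'   `count`, `distinct_reads`, `min_qual`), `qual_sums` (integer matrix,
#'   one row per vertex), and `edges` (data.table `from`, `to`, `freq`).
#' @export
build_graph <- function(reads, k, quals = NULL, both_strands = TRUE) {
  if (is.character(reads)) {
    seqs <- reads
    if (is.null(quals))
      quals <- vapply(nchar(seqs), function(n) strrep("D", n), character(1))
  } else {
    rs <- as.data.table(reads)
    seqs <- rs$seq
    quals <- rs$qual
  }
  stopifnot(length(seqs) == length(quals))
  n_short <- sum(nchar(seqs) < k)
  if (n_short > 0L)
    warning(n_short, " read(s) shorter than k=", k, " skipped")
  res <- .dbg_count_kmers(seqs, quals, as.integer(k), both_strands)
  vertices <- data.table(kmer = res$kmer, count = res$count,
                         distinct_reads = res$distinct_reads)
  qs <- res$qual_sums
  vertices[, min_qual := if (nrow(qs) > 0L) apply(qs, 1L, min) else integer(0)]
  edges <- data.table(
    from = substring(res$edge_kmer, 1L, k),
    to = substring(res$edge_kmer, 2L, k + 1L),
    freq = res$edge_freq
  )
  structure(list(k = as.integer(k), vertices = vertices, qual_sums = qs,
                 edges = edges),
            class = "kmer_graph")
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat("kmer_graph: k =", x$k, "|", nrow(x$vertices), "vertices,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Prune the de Bruijn graph
#'
#' Removes vertices whose observation count is below `min_count`, whose
#' summed base quality at any k-mer position is below `min_qual_sum`, or
#' that are supported by no more than one distinct read. Incident edges are
#' removed with their vertices.
#'
#' @param g a `kmer_graph`.
#' @param min_count minimum total observations (default 2).
#' @param min_qual_sum minimum per-position quality sum (default 60).
#' @param min_distinct minimum distinct supporting reads (default 2; the
#'   single-read pruning rule).
#' @return a pruned `kmer_graph`.
#' @export
prune_graph <- function(g, min_count = 2L, min_qual_sum = 60L,
                        min_distinct = 2L) {
  stopifnot(min_count >= 0L, min_qual_sum >= 0L)
  v <- g$vertices
  keep <- v$count >= min_count & v$min_qual >= min_qual_sum &
    v$distinct_reads >= min_distinct
  vertices <- v[keep]
  qs <- g$qual_sums[keep, , drop = FALSE]
  edges <- g$edges[from %chin% vertices$kmer & to %chin% vertices$kmer]
  structure(list(k = g$k, vertices = vertices, qual_sums = qs, edges = edges),
            class = "kmer_graph")
}

#' Condense linear paths
#'
#' Maximal chains of vertices with at most one incoming and one outgoing edge
#' are merged into single nodes spelling the chain's sequence; branch
#' vertices (in-degree or out-degree above one) always remain their own
#' nodes. Chain cycles are broken deterministically at the lexicographically
#' smallest k-mer (the cycle-closing edge is dropped).
#'
#' @param g a pruned `kmer_graph`.
#' @return a `condensed_graph`: list with `k`, `nodes` (data.table `id`,
#'   `seq`, `n_kmers`, `min_count`, `first_kmer`, `last_kmer`) and `edges`
#'   (data.table `from`, `to`, `freq` over node ids).
#' @export
condense <- function(g) {
  v <- g$vertices
  e <- g$edges
  k <- g$k
  if (nrow(v) == 0L) {
    return(structure(list(k = k,
                          nodes = data.table(id = character(0), seq = character(0),
                                             n_kmers = integer(0), min_count = integer(0),
                                             first_kmer = character(0), last_kmer = character(0)),
                          edges = data.table(from = character(0), to = character(0),
                                             freq = integer(0))),
                     class = "condensed_graph"))
  }
  indeg <- setNames(rep(0L, nrow(v)), v$kmer)
  outdeg <- setNames(rep(0L, nrow(v)), v$kmer)
  if (nrow(e) > 0L) {
    ti <- e[, .N, by = to];   indeg[ti$to] <- ti$N
    to_ <- e[, .N, by = from]; outdeg[to_$from] <- to_$N
  }
  linear <- indeg <= 1L & outdeg <= 1L
  # an edge a->b is mergeable when both ends are linear and the step is forced
  mergeable <- if (nrow(e) > 0L)
    linear[e$from] & linear[e$to] else logical(0)
  chain_e <- e[mergeable]
  drop_edge <- rep(FALSE, nrow(chain_e))

  member <- setNames(seq_len(nrow(v)), v$kmer)   # vertex -> chain id (init: own)
  if (nrow(chain_e) > 0L) {
    gr <- igraph::graph_from_data_frame(chain_e[, .(from, to)], directed = TRUE,
                                        vertices = data.frame(name = v$kmer))
    comp <- igraph::components(gr, mode = "weak")$membership
    member[] <- comp[v$kmer]
  }
  # order each multi-vertex chain from its head; break pure cycles
  nxt <- setNames(chain_e$to, chain_e$from)
  has_chain_in <- setNames(rep(FALSE, nrow(v)), v$kmer)
  has_chain_in[chain_e$to] <- TRUE
  counts <- setNames(v$count, v$kmer)

  chains <- split(v$kmer, member)
  spell_chain <- function(kms) {
    if (length(kms) == 1L)
      return(list(seq = kms, kms = kms))
    heads <- kms[!has_chain_in[kms]]
    if (length(heads) == 0L) {           # chain cycle
      head_km <- min(kms)
      drop <- which(chain_e$to == head_km)
      drop_edge[drop] <<- TRUE
    } else head_km <- heads[1]
    ord <- character(length(kms))
    cur <- head_km
    for (i in seq_along(kms)) {
      ord[i] <- cur
      cur <- if (i < length(kms)) nxt[[cur]] else NA_character_
    }
    list(seq = paste0(ord[1], paste(substring(ord[-1], k, k), collapse = "")),
         kms = ord)
  }
  spelled <- lapply(chains, spell_chain)
  nodes <- data.table(
    id = paste0("n", seq_along(spelled)),
    seq = vapply(spelled, `[[`, character(1), "seq"),
    n_kmers = vapply(spelled, function(s) length(s$kms), integer(1)),
    min_count = vapply(spelled, function(s) min(counts[s$kms]), integer(1)),
    first_kmer = vapply(spelled, function(s) s$kms[1], character(1)),
    last_kmer = vapply(spelled, function(s) s$kms[length(s$kms)], character(1))
  )
  node_of <- setNames(rep(nodes$id, nodes$n_kmers),
                      unlist(lapply(spelled, `[[`, "kms"), use.names = FALSE))
  # condensed edges: all original edges that were not merged into a chain
  merged <- chain_e[!drop_edge]
  if (nrow(e) > 0L) {
    key_all <- paste(e$from, e$to)
    key_merged <- if (nrow(merged) > 0L) paste(merged$from, merged$to) else character(0)
    rest <- e[!key_all %chin% key_merged]
    cedges <- data.table(from = unname(node_of[rest$from]),
                         to = unname(node_of[rest$to]),
                         freq = rest$freq)
  } else {
    cedges <- data.table(from = character(0), to = character(0), freq = integer(0))
  }
  structure(list(k = k, nodes = nodes, edges = cedges),
            class = "condensed_graph")
}

#' @export
print.condensed_graph <- function(x, ...) {
  cat("condensed_graph: k =", x$k, "|", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Dump a condensed graph as GFA 1.0
#'
#' Segments are condensed nodes, links are edges (overlap k-1).
#'
#' @param g a `condensed_graph`.
#' @param path output file.
#' @export
write_gfa <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("H\tVN:Z:1.0", con)
  writeLines(paste("S", g$nodes$id, g$nodes$seq,
                   paste0("RC:i:", g$nodes$min_count), sep = "\t"), con)
  if (nrow(g$edges) > 0L)
    writeLines(paste("L", g$edges$from, "+", g$edges$to, "+",
                     paste0(g$k - 1L, "M"), paste0("RC:i:", g$edges$freq),
                     sep = "\t"), con)
  invisible(path)
}
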