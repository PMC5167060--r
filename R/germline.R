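#' Load a germline segment database
#'
#' Reads germline V/D/J/C segments from a FASTA file plus a tab-separated
#' metadata sidecar with columns `id`, `chain` (IGH/IGK/IGL), `class`
#' (V/D/J/C), `functional` (logical) and `frame_offset` (0-2, V segments
#' only; the position within the segment where codons start). Every FASTA
#' record must have a metadata row. Non-functional segments are retained but
#' flagged and excluded from k-mer indexing and anchor extraction.
#'
#' @param fasta_path path to the segment FASTA.
#' @param metadata_path path to the TSV sidecar.
#' @param chain restrict the database to one chain (default: keep all).
#' @return an object of class `germline_db`: a list with `segments` (a
#'   data.table) and `chain`.
#' @export
load_germline <- function(fasta_path, metadata_path, chain = NULL) {
  if (!file.exists(fasta_path)) stop("germline FASTA not found: ", fasta_path)
  if (!file.exists(metadata_path)) stop("germline metadata not found: ", metadata_path)
  seqs <- read_fasta(fasta_path)
  if (length(seqs) == 0L) stop("empty germline FASTA: ", fasta_path)
  # FASTA headers may carry descriptions after the id
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  meta <- fread(metadata_path, sep = "\t", header = TRUE,
                colClasses = list(character = c("id", "chain", "class")))
  required <- c("id", "chain", "class", "functional", "frame_offset")
  if (!all(required %in% names(meta)))
    stop("metadata must have columns: ", paste(required, collapse = ", "))
  missing <- setdiff(names(seqs), meta$id)
  if (length(missing) > 0L)
    stop("no metadata row for FASTA record(s): ", paste(missing, collapse = ", "))
  meta <- meta[id %chin% names(seqs)]
  bad <- grepl("[^ACGTN]", seqs[meta$id])
  if (any(bad)) {
    offending <- gsub("[ACGTN]", "", seqs[meta$id][bad][1])
    stop("record ", meta$id[bad][1], " contains invalid character(s): ",
         substr(offending, 1, 5))
  }
  segments <- data.table(
    id = meta$id,
    chain = meta$chain,
    seg_class = meta$class,
    sequence = unname(seqs[meta$id]),
    functional = as.logical(meta$functional),
    frame_offset = suppressWarnings(as.integer(meta$frame_offset))
  )
  if (!is.null(chain)) segments <- segments[segments$chain == chain]
  stopifnot(all(segments$seg_class %in% c("V", "D", "J", "C")))
  if (any(segments$seg_class == "V" & is.na(segments$frame_offset)))
    stop("V segments must carry a frame_offset")
  validate_segment_lengths(segments)
  db <- structure(list(segments = segments,
                       chain = if (is.null(chain)) unique(segments$chain) else chain),
                  class = "germline_db")
  db
}

validate_segment_lengths <- function(segments) {
  len <- nchar(segments$sequence)
  if (any(len == 0L)) stop("empty sequence for segment ", segments$id[len == 0L][1])
  short_v <- segments$seg_class == "V" & len < 50L
  if (any(short_v)) stop("V segment shorter than 50 nt: ", segments$id[short_v][1])
  short_j <- segments$seg_class == "J" & len < 20L
  if (any(short_j)) stop("J segment shorter than 20 nt: ", segments$id[short_j][1])
  invisible(TRUE)
}

#' Write a germline database back to FASTA + metadata
#'
#' @param db a `germline_db`.
#' @param fasta_path,metadata_path output paths.
#' @export
write_germline <- function(db, fasta_path, metadata_path) {
  s <- db$segments
  write_fasta(setNames(s$sequence, s$id), fasta_path)
  out <- data.table(id = s$id, chain = s$chain, class = s$seg_class,
                    functional = s$functional, frame_offset = s$frame_offset)
  fwrite(out, metadata_path, sep = "\t", na = "NA", quote = FALSE)
  invisible(list(fasta = fasta_path, metadata = metadata_path))
}

#' @export
print.germline_db <- function(x, ...) {
  tab <- table(x$segments$seg_class)
  cat("germline_db:", nrow(x$segments), "segments (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ") chain:",
      paste(x$chain, collapse = ","), "\n")
  invisible(x)
}

#' Build the germline k-mer extraction index
#'
#' Collects every length-`k` substring of each functional V/D/J segment of
#' the configured chain, together with the k-mers of the reverse complement
#' (RNA-seq reads arrive in both orientations). Segments shorter than `k`
#' contribute nothing (with a warning).
#'
#' @param db a `germline_db`.
#' @param k k-mer length (default 15).
#' @return character vector: the sorted unique k-mer set.
#' @export
build_kmer_index <- function(db, k = 15L) {
  stopifnot(k >= 8L)
  s <- db$segments[functional & seg_class %chin% c("V", "D", "J")]
  if (nrow(s) == 0L) return(character(0))
  too_short <- nchar(s$sequence) < k
  if (any(too_short))
    warning(sum(too_short), " segment(s) shorter than k=", k,
            " contribute no k-mers")
  seqs <- s$sequence[!too_short]
  if (length(seqs) == 0L) return(character(0))
  fwd <- unlist(lapply(seqs, kmers_of, k = k), use.names = FALSE)
  rev <- unlist(lapply(revcomp(seqs), kmers_of, k = k), use.names = FALSE)
  sort(unique(c(fwd, rev)))
}

#' Extract V/J anchors
#'
#' A 16-base anchor is taken from near the 3' end of each functional V
#' segment and near the 5' end of each functional J segment. `v_end_offset`
#' / `j_start_offset` back the anchor away from the segment terminus so that
#' junctional exonuclease trimming does not erode it. Identical anchor
#' strings are deduplicated with multi-segment attribution.
#'
#' @param db a `germline_db`.
#' @param anchor_len anchor length (default 16).
#' @param v_end_offset bases skipped from the V 3' end (default 8).
#' @param j_start_offset bases skipped from the J 5' start (default 8).
#' @return an `anchor_set`: list with data.tables `v_anchors` and
#'   `j_anchors` (columns `anchor`, `segments` (list), `offset`).
#' @export
extract_anchors <- function(db, anchor_len = 16L, v_end_offset = 8L,
                            j_start_offset = 8L) {
  segs <- db$segments[functional == TRUE]
  one_side <- function(cls, get_anchor, off) {
    s <- segs[seg_class == cls]
    if (nrow(s) == 0L) return(data.table(anchor = character(0),
                                         segments = list(), offset = integer(0)))
    len <- nchar(s$sequence)
    ok <- len >= anchor_len + off
    if (any(!ok))
      warning(sum(!ok), " ", cls, " segment(s) too short for an anchor; skipped")
    s <- s[ok]
    if (nrow(s) == 0L) return(data.table(anchor = character(0),
                                         segments = list(), offset = integer(0)))
    a <- get_anchor(s$sequence)
    dt <- data.table(anchor = a, segment = s$id)
    dt[, .(segments = list(segment), offset = off), by = anchor]
  }
  v <- one_side("V", function(x) {
    n <- nchar(x)
    substring(x, n - v_end_offset - anchor_len + 1L, n - v_end_offset)
  }, v_end_offset)
  j <- one_side("J", function(x) {
    substring(x, j_start_offset + 1L, j_start_offset + anchor_len)
  }, j_start_offset)
  structure(list(v_anchors = v, j_anchors = j, anchor_len = anchor_len,
                 v_end_offset = v_end_offset, j_start_offset = j_start_offset),
            class = "anchor_set")
}

# segments of one class, as named character vector
germline_seqs <- function(db, cls, functional_only = TRUE) {
  s <- db$segments[seg_class == cls]
  if (functional_only) s <- s[functional == TRUE]
  setNames(s$sequence, s$id)
}
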