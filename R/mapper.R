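## Minimal seed-and-extend mapper and local aligner. The mapper reports a
## three-valued mapping quality {0, 30, 60}: 60 for a unique locus with no
## qualifying second, 30 for a unique best with a weaker second, 0 for ties.
## The pipeline only ever consumes the >= 30 threshold.

#' Build a k-mer seed index over target sequences
#'
#' Exact k-mers (default 21) mapped to their positions on the forward strand
#' of every target; queries are searched on both strands. k-mers containing N
#' are never indexed.
#'
#' @param seqs Named character vector of target sequences.
#' @param k Seed length (11-31).
#' @return An object of class `seq_index`.
#' @export
seq_index <- function(seqs, k = 21L) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  ptr <- cpp_index_build(unname(seqs), names(seqs), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), targets = names(seqs),
                 lengths = setNames(nchar(seqs), names(seqs))),
            class = "seq_index")
}

#' @export
print.seq_index <- function(x, ...) {
  cat("seq_index: ", length(x$targets), " target(s), k = ", x$k,
      ", total ", sum(x$lengths), " bp\n", sep = "")
  invisible(x)
}

#' Map reads against a seed index
#'
#' Seeds are chained per (target, strand, diagonal); the best candidates are
#' extended with banded alignment (band 15% of the read length). A read is
#' unmapped when its best identity falls below `min_identity`.
#'
#' @param index A [seq_index()].
#' @param reads Character vector of read sequences (names used as ids).
#' @param min_identity Minimum matches / read length to report an alignment.
#' @param max_candidates Seed-cluster candidates extended per read.
#' @param stride Query seed stride in bp.
#' @param max_occ Seeds occurring more often than this in the index are
#'   skipped as repetitive.
#' @return data.frame with one row per read: `query_id`, `mapped`, `target`,
#'   `pos` (0-based), `ref_end`, `strand`, `mapq`, `score`, `identity`,
#'   `aln_len`, `cigar`, `n_candidates`.
#' @export
map_reads <- function(index, reads, min_identity = 0.9, max_candidates = 8L,
                      stride = 3L, max_occ = 64L) {
  stopifnot(inherits(index, "seq_index"))
  ids <- if (is.null(names(reads))) as.character(seq_along(reads)) else names(reads)
  df <- cpp_map_reads(index$ptr, unname(reads), min_identity,
                      0.15, as.integer(max_candidates), as.integer(stride),
                      as.integer(max_occ))
  df$target <- index$targets[df$target]
  cbind(data.frame(query_id = ids, stringsAsFactors = FALSE), df)
}

#' Local alignment of a query against a target window
#'
#' Full Smith-Waterman (match +1, mismatch -1, gap -2) with iterative masking
#' to report up to `max_hits` non-overlapping local alignments, each with
#' identity (matches over aligned columns) and query coverage. Ties are
#' resolved toward the lowest target coordinate.
#'
#' @param query Query sequence (non-empty).
#' @param target Target window sequence.
#' @param min_score Minimum alignment score to report.
#' @param max_hits Maximum number of alignments.
#' @return data.frame with `qstart`, `qend`, `tstart`, `tend` (0-based
#'   half-open), `score`, `matches`, `aln_len`, `identity`, `coverage`.
#' @export
align_local <- function(query, target, min_score = 20L, max_hits = 5L) {
  if (is.na(query) || nchar(query) == 0) stop("empty query")
  cpp_sw_local(query, target, as.integer(min_score), as.integer(max_hits))
}

#' Convert a mate's alignment table to SAM records
#'
#' @param aln Alignment table from [map_reads()].
#' @param seqs,quals Read sequences and qualities in `aln` order.
#' @param mate Mate number (1 or 2) for the FLAG bits.
#' @param mate_mapped Logical vector: is the other mate mapped?
#' @return data.frame of SAM fields suitable for [write_sam()].
#' @export
alignments_to_sam <- function(aln, seqs, quals, mate = 1L,
                              mate_mapped = rep(TRUE, nrow(aln))) {
  flag <- 1L +                                   # paired
    ifelse(aln$mapped, 0L, 4L) +                 # unmapped
    ifelse(mate_mapped, 0L, 8L) +                # mate unmapped
    ifelse(aln$mapped & aln$strand == "-", 16L, 0L) +
    if (mate == 1L) 64L else 128L
  data.frame(qname = aln$query_id, flag = flag,
             rname = ifelse(aln$mapped, aln$target, NA),
             pos = ifelse(aln$mapped, aln$pos, NA),
             mapq = ifelse(aln$mapped, aln$mapq, 0L),
             cigar = ifelse(aln$mapped, aln$cigar, NA),
             seq = seqs, qual = quals, stringsAsFactors = FALSE)
}
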