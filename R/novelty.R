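## Novelty screening: remove contigs already present verbatim in the
## reference (exact containment in either orientation), record best
## identity/coverage for the rest, and measure cross-sample (outgroup)
## support to separate reference gaps/errors from group-specific sequence.

#' Screen contigs against the reference
#'
#' A contig found as an exact substring of the reference (either orientation)
#' is `KNOWN` (identity 1, coverage 1) and removed from the novel set. For
#' the rest, the best local alignment in the best seed-candidate window is
#' recorded: `PARTIAL` when coverage and identity clear the thresholds,
#' otherwise `NOVEL`. Partial contigs are retained in the novel set, with
#' identity and coverage reported for downstream filtering.
#'
#' @param contigs data.frame with `contig_id`, `sequence`.
#' @param reference Named character vector of reference sequences.
#' @param index Optional prebuilt [seq_index()] of the reference.
#' @param min_partial_coverage,min_partial_identity Thresholds for `PARTIAL`.
#' @return list with `verdicts` (data.frame: `contig_id`, `status`,
#'   `best_identity`, `best_coverage`) and `novel` (contigs minus `KNOWN`).
#' @export
screen_reference <- function(contigs, reference, index = NULL,
                             min_partial_coverage = 0.5,
                             min_partial_identity = 0.95) {
  n <- nrow(contigs)
  status <- character(n)
  best_id <- numeric(n)
  best_cov <- numeric(n)
  if (n > 0) {
    subjects <- lapply(reference, Biostrings::DNAString)
    if (is.null(index)) index <- seq_index(reference)
    for (i in seq_len(n)) {
      s <- contigs$sequence[i]
      pats <- c(s, as.character(cpp_revcomp(s)))
      exact <- any(vapply(subjects, function(subj)
        any(vapply(pats, function(p)
          Biostrings::countPattern(p, subj, fixed = TRUE) > 0, logical(1))),
        logical(1)))
      if (exact) {
        status[i] <- "KNOWN"; best_id[i] <- 1; best_cov[i] <- 1
        next
      }
      cand <- map_reads(index, setNames(s, contigs$contig_id[i]),
                        min_identity = 0)
      if (!isTRUE(cand$mapped[1])) {
        status[i] <- "NOVEL"; best_id[i] <- 0; best_cov[i] <- 0
        next
      }
      L <- nchar(s)
      tlen <- index$lengths[[cand$target[1]]]
      ws <- max(0, cand$pos[1] - L)
      we <- min(tlen, cand$ref_end[1] + L)
      win <- substr(reference[[cand$target[1]]], ws + 1, we)
      hits <- align_local(s, win, min_score = 20L, max_hits = 1L)
      # the seeds came from one strand; check the reverse orientation too
      hits_rc <- align_local(as.character(cpp_revcomp(s)), win,
                             min_score = 20L, max_hits = 1L)
      hits <- rbind(hits, hits_rc)
      if (nrow(hits) == 0) {
        status[i] <- "NOVEL"; best_id[i] <- 0; best_cov[i] <- 0
        next
      }
      b <- hits[order(-hits$score, hits$tstart)[1], ]
      best_id[i] <- b$identity
      best_cov[i] <- b$coverage
      if (b$identity == 1 && b$coverage == 1) status[i] <- "KNOWN"
      else if (b$coverage >= min_partial_coverage &&
               b$identity >= min_partial_identity) status[i] <- "PARTIAL"
      else status[i] <- "NOVEL"
    }
  }
  verdicts <- data.frame(contig_id = contigs$contig_id, status = status,
                         best_identity = best_id, best_coverage = best_cov,
                         stringsAsFactors = FALSE)
  list(verdicts = verdicts,
       novel = contigs[status != "KNOWN", , drop = FALSE])
}

#' Cross-sample (outgroup) support for contigs
#'
#' Aligns outgroup reads to the contigs and reports, per contig, the fraction
#' of bases covered by alignments with mapping quality at least `min_mapq`,
#' plus the overall fraction of contigs with any qualifying alignment. High
#' outgroup coverage marks contigs that reflect reference gaps or errors
#' rather than group-specific novel sequence.
#'
#' @param contigs data.frame with `contig_id`, `sequence`.
#' @param outgroup_reads Character vector of outgroup read sequences (or a
#'   paired-read table, in which case both mates are used).
#' @param min_mapq Mapping-quality threshold.
#' @param min_identity Mapper identity threshold.
#' @return list with `coverage` (data.frame: `contig_id`, `covered_fraction`,
#'   `n_reads`) and `summary` (fraction of contigs with any qualifying
#'   alignment).
#' @export
cross_sample_support <- function(contigs, outgroup_reads, min_mapq = 30L,
                                 min_identity = 0.9) {
  if (is.data.frame(outgroup_reads))
    outgroup_reads <- c(outgroup_reads$seq1, outgroup_reads$seq2)
  cov <- data.frame(contig_id = contigs$contig_id,
                    covered_fraction = 0, n_reads = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(contigs) == 0 || length(outgroup_reads) == 0)
    return(list(coverage = cov, summary = if (nrow(contigs) > 0) 0 else NA_real_))
  idx <- seq_index(setNames(contigs$sequence, contigs$contig_id),
                   k = min(21L, max(11L, min(nchar(contigs$sequence)) - 1L)))
  aln <- map_reads(idx, outgroup_reads, min_identity = min_identity)
  aln <- aln[aln$mapped %in% TRUE & aln$mapq >= min_mapq, , drop = FALSE]
  for (i in seq_len(nrow(contigs))) {
    a <- aln[aln$target == contigs$contig_id[i], , drop = FALSE]
    cov$n_reads[i] <- nrow(a)
    if (nrow(a) > 0) {
      ir <- IRanges::reduce(IRanges::IRanges(a$pos + 1L, a$ref_end))
      cov$covered_fraction[i] <- sum(IRanges::width(ir)) /
        nchar(contigs$sequence[i])
    }
  }
  list(coverage = cov, summary = mean(cov$n_reads > 0))
}
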