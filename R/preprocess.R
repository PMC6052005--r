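## Read pre-processing: quality trimming and triage of aligned pairs into
## mapped / one-end-anchored / both-unmapped classes.

#' Trimming policy
#'
#' Sliding-window quality trimming: leading and trailing bases at or below
#' `end_clip_max_phred` are clipped; then, scanning 5' to 3', the read is cut
#' at the first `window`-base window whose mean phred falls below
#' `window_min_mean_phred` (bases at the window start keep being retained
#' while individually at or above the threshold, matching the conventional
#' sliding-window trimmer). Results shorter than `min_length` are discarded.
#'
#' @param window Window size in bases.
#' @param window_min_mean_phred Minimum mean phred per window.
#' @param end_clip_max_phred Maximum phred of clippable end bases.
#' @param min_length Minimum surviving read length.
#' @return An object of class `trim_policy`.
#' @export
trim_policy <- function(window = 4L, window_min_mean_phred = 20,
                        end_clip_max_phred = 3L, min_length = 50L) {
  stopifnot(window >= 1, min_length >= 1)
  structure(list(window = as.integer(window),
                 window_min_mean_phred = window_min_mean_phred,
                 end_clip_max_phred = as.integer(end_clip_max_phred),
                 min_length = as.integer(min_length)),
            class = "trim_policy")
}

#' Quality-trim reads
#'
#' @param seqs,quals Parallel character vectors (phred+33 qualities).
#' @param policy A [trim_policy()].
#' @return data.frame with `seq`, `qual`, `keep`; discarded reads have
#'   `keep = FALSE` and empty sequences.
#' @export
trim_reads <- function(seqs, quals, policy = trim_policy()) {
  if (length(seqs) != length(quals))
    stop("seqs and quals must have the same length")
  r <- cpp_trim_reads(seqs, quals, policy$window,
                      policy$window_min_mean_phred,
                      policy$end_clip_max_phred, policy$min_length)
  data.frame(seq = r$sequence, qual = r$quality, keep = r$keep,
             stringsAsFactors = FALSE)
}

#' Trim both mates of a paired-read table
#'
#' A pair is kept only when both mates survive trimming; pairs losing either
#' mate are counted as discarded.
#'
#' @param reads Paired-read data.frame.
#' @param policy A [trim_policy()].
#' @return list with `reads` (surviving pairs, trimmed) and `n_discarded`.
#' @export
trim_pairs <- function(reads, policy = trim_policy()) {
  t1 <- trim_reads(reads$seq1, reads$qual1, policy)
  t2 <- trim_reads(reads$seq2, reads$qual2, policy)
  keep <- t1$keep & t2$keep
  out <- data.frame(id = reads$id[keep],
                    seq1 = t1$seq[keep], qual1 = t1$qual[keep],
                    seq2 = t2$seq[keep], qual2 = t2$qual[keep],
                    stringsAsFactors = FALSE)
  list(reads = out, n_discarded = sum(!keep))
}

#' Classify aligned read pairs
#'
#' A pair is `MAPPED_CONCORDANT` when both mates map to the same target on
#' opposite strands in forward-reverse orientation with an implied insert
#' within tolerance of `insert_mean`; `OEA` when exactly one mate maps;
#' `BOTH_UNMAPPED` when neither does. Pairs with both mates mapped but a
#' discordant geometry are routed to the unaligned pool (class
#' `BOTH_UNMAPPED`) and flagged in the `discordant` column.
#'
#' @param aln1,aln2 Alignment tables from [map_reads()] for mate 1 and 2, in
#'   pair order.
#' @param insert_mean Expected insert size (bp).
#' @param insert_tolerance Multiplier: inserts within
#'   `[insert_mean / insert_tolerance, insert_mean * insert_tolerance]` count
#'   as concordant.
#' @return data.frame with `class` (factor) and `discordant` (logical).
#' @export
classify_pairs <- function(aln1, aln2, insert_mean = 290L,
                           insert_tolerance = 3) {
  stopifnot(nrow(aln1) == nrow(aln2))
  m1 <- aln1$mapped %in% TRUE
  m2 <- aln2$mapped %in% TRUE
  n <- nrow(aln1)
  cls <- rep("BOTH_UNMAPPED", n)
  disc <- rep(FALSE, n)
  cls[xor(m1, m2)] <- "OEA"
  both <- m1 & m2
  if (any(both)) {
    same <- both & aln1$target == aln2$target &
      aln1$strand != aln2$strand
    fwd_pos <- ifelse(aln1$strand == "+", aln1$pos, aln2$pos)
    rev_end <- ifelse(aln1$strand == "+", aln2$ref_end, aln1$ref_end)
    ins <- rev_end - fwd_pos
    conc <- same & !is.na(ins) & ins >= insert_mean / insert_tolerance &
      ins <= insert_mean * insert_tolerance
    conc[is.na(conc)] <- FALSE
    cls[both & conc] <- "MAPPED_CONCORDANT"
    disc[both & !conc] <- TRUE
  }
  data.frame(class = factor(cls, levels = c("MAPPED_CONCORDANT", "OEA",
                                            "BOTH_UNMAPPED", "DISCARDED")),
             discordant = disc)
}

#' Extract the unaligned pool and the OEA sidecar
#'
#' Pairs classified `BOTH_UNMAPPED` (including, by default, discordant pairs)
#' form the assembly pool. `OEA` pairs are retained separately: the mapped
#' mate's genome coordinates anchor the unmapped mate's future contig.
#'
#' @param reads Trimmed paired-read table.
#' @param aln1,aln2 Alignment tables for the two mates.
#' @param classes Classification from [classify_pairs()].
#' @param include_discordant Include discordant both-mapped pairs in the pool.
#' @param n_discarded Count of pairs removed by trimming (for the class table).
#' @return list with `pool` (paired-read table), `oea` (data.frame: pair id,
#'   genome-side coordinates of the anchored mate, sequence/quality of the
#'   unanchored mate) and `counts` (named class counts summing to the total).
#' @export
extract_unaligned_pool <- function(reads, aln1, aln2, classes,
                                   include_discordant = TRUE,
                                   n_discarded = 0L) {
  stopifnot(nrow(reads) == nrow(classes))
  pool_sel <- classes$class == "BOTH_UNMAPPED" &
    (include_discordant | !classes$discordant)
  pool <- reads[pool_sel, , drop = FALSE]
  oea_sel <- classes$class == "OEA"
  m1 <- aln1$mapped %in% TRUE
  anchored1 <- oea_sel & m1
  anchored2 <- oea_sel & !m1
  ga <- rbind(
    data.frame(pair_id = reads$id[anchored1],
               g_target = aln1$target[anchored1], g_pos = aln1$pos[anchored1],
               g_end = aln1$ref_end[anchored1],
               g_strand = aln1$strand[anchored1],
               g_mapq = aln1$mapq[anchored1],
               mate_seq = reads$seq2[anchored1],
               mate_qual = reads$qual2[anchored1],
               anchored_mate = rep(1L, sum(anchored1)),
               stringsAsFactors = FALSE),
    data.frame(pair_id = reads$id[anchored2],
               g_target = aln2$target[anchored2], g_pos = aln2$pos[anchored2],
               g_end = aln2$ref_end[anchored2],
               g_strand = aln2$strand[anchored2],
               g_mapq = aln2$mapq[anchored2],
               mate_seq = reads$seq1[anchored2],
               mate_qual = reads$qual1[anchored2],
               anchored_mate = rep(2L, sum(anchored2)),
               stringsAsFactors = FALSE))
  counts <- c(MAPPED_CONCORDANT = sum(classes$class == "MAPPED_CONCORDANT"),
              OEA = sum(oea_sel),
              BOTH_UNMAPPED = sum(classes$class == "BOTH_UNMAPPED"),
              DISCARDED = as.integer(n_discarded))
  list(pool = pool, oea = ga[order(ga$pair_id), , drop = FALSE],
       counts = counts)
}
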