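## One-end-anchor placement: a read pair with one mate on the genome and the
## other on a contig predicts where the contig belongs, by fragment-length
## arithmetic. Anchors are clustered per contig, contigs classified by locus
## multiplicity, and single-locus predictions verified by local realignment.

#' Harvest one-end anchors
#'
#' Joins the genome side of OEA pairs (from [extract_unaligned_pool()]) with
#' the alignments of their unanchored mates to the contigs. An anchor is
#' emitted only when both sides reach `min_mapq` — the uniqueness filter on
#' both the genome and the assembly. The contig end (5' or 3') is assigned by
#' whether the contig-side mate lies within `insert_mean` bases of the
#' contig's start or end.
#'
#' @param oea OEA sidecar data.frame (`pair_id`, `g_target`, `g_pos`,
#'   `g_end`, `g_strand`, `g_mapq`, `mate_seq`, ...).
#' @param contig_aln [map_reads()] result for `oea$mate_seq` against the
#'   contigs, in the same row order.
#' @param contig_lengths Named vector of contig lengths.
#' @param min_mapq Mapping-quality threshold applied to both sides.
#' @param insert_mean Expected insert size (bp).
#' @return Anchor data.frame; attribute `counts` records how many candidate
#'   pairs each filter removed.
#' @export
harvest_anchors <- function(oea, contig_aln, contig_lengths,
                            min_mapq = 30L, insert_mean = 290L) {
  stopifnot(nrow(oea) == nrow(contig_aln))
  g_ok <- oea$g_mapq >= min_mapq
  c_mapped <- contig_aln$mapped %in% TRUE
  c_ok <- c_mapped & contig_aln$mapq >= min_mapq
  keep <- g_ok & c_ok
  counts <- c(candidates = nrow(oea),
              low_genome_mapq = sum(!g_ok),
              mate_unmapped_on_contigs = sum(g_ok & !c_mapped),
              low_contig_mapq = sum(g_ok & c_mapped & !c_ok),
              anchors = sum(keep))
  a <- data.frame(pair_id = oea$pair_id[keep],
                  g_target = oea$g_target[keep],
                  g_pos = oea$g_pos[keep], g_end = oea$g_end[keep],
                  g_strand = oea$g_strand[keep], g_mapq = oea$g_mapq[keep],
                  c_id = contig_aln$target[keep],
                  c_pos = contig_aln$pos[keep],
                  c_end = contig_aln$ref_end[keep],
                  c_strand = contig_aln$strand[keep],
                  c_mapq = contig_aln$mapq[keep],
                  stringsAsFactors = FALSE)
  a$contig_len <- as.integer(contig_lengths[a$c_id])
  near5 <- a$c_pos < insert_mean
  near3 <- a$c_end > a$contig_len - insert_mean
  a$contig_end <- ifelse(near5 & near3,
                         ifelse(a$c_pos <= a$contig_len - a$c_end,
                                "FIVE_PRIME", "THREE_PRIME"),
                         ifelse(near5, "FIVE_PRIME",
                                ifelse(near3, "THREE_PRIME", "INTERNAL")))
  attr(a, "counts") <- counts
  a
}

#' Predict a contig's genomic interval from one anchor
#'
#' Fragment-length arithmetic. With `g` the genome mate's leftmost 0-based
#' position: on `+` the fragment extends right and the missing mate's
#' expected leftmost genome position is `m = g + insert_mean - c_len`
#' (`c_len` = contig-side read length); on `-` it is
#' `m = g + g_len - insert_mean` (`g_len` = genome-side aligned length). The
#' missing mate's expected genome strand is the opposite of the anchored
#' mate's; when the contig-side strand equals it the contig is
#' genome-forward and its predicted start is `m - c`, otherwise the contig
#' is flipped and the start is `m + c + c_len - contig_len`, with `c` the
#' contig-side leftmost position. The predicted interval is
#' `[start, start + contig_len)`.
#'
#' @param anchors Anchor data.frame from [harvest_anchors()].
#' @param insert_mean Expected insert size (bp).
#' @return `anchors` with added `pred_start`, `pred_end`, `orientation`.
#' @export
predict_locus <- function(anchors, insert_mean = 290L) {
  c_len <- anchors$c_end - anchors$c_pos
  g_len <- anchors$g_end - anchors$g_pos
  m <- ifelse(anchors$g_strand == "+",
              anchors$g_pos + insert_mean - c_len,
              anchors$g_pos + g_len - insert_mean)
  expected <- ifelse(anchors$g_strand == "+", "-", "+")
  forward <- anchors$c_strand == expected
  start <- ifelse(forward, m - anchors$c_pos,
                  m + anchors$c_pos + c_len - anchors$contig_len)
  anchors$pred_start <- as.integer(round(start))
  anchors$pred_end <- anchors$pred_start + anchors$contig_len
  anchors$orientation <- ifelse(forward, "+", "-")
  anchors
}

single_linkage_1d <- function(values, radius) {
  ord <- order(values)
  brk <- c(0, which(diff(values[ord]) > radius), length(values))
  lapply(seq_len(length(brk) - 1), function(i) ord[(brk[i] + 1):brk[i + 1]])
}

#' Cluster anchor predictions and classify contigs by locus multiplicity
#'
#' Anchors are grouped per (contig, target) and by which genome-side end of
#' the placement they witness: an anchor at the contig end that faces left
#' on the genome estimates the contig's reference start, one at the
#' genome-right end estimates its reference end. Each group is clustered by
#' single linkage within `cluster_radius`, and a left cluster is reconciled
#' with a compatible right cluster (same orientation, separation between
#' zero reference span and the contig length, within the radius) into a
#' single locus whose interval is the reference span the contig corresponds
#' to: the full span for a collinear (gap-filling) contig, a short
#' junction interval for an inserted contig whose two ends anchor the same
#' reference point. Loci supported by fewer than `min_support` anchors are
#' dropped. Contigs are classified `SINGLE`, `TWO`, `MULTI` (more than two
#' loci) or `UNPLACED`.
#'
#' @param pred Anchor table with predictions from [predict_locus()].
#' @param contig_ids All contig ids under consideration (so contigs without
#'   anchors are reported `UNPLACED`).
#' @param cluster_radius Single-linkage radius (default `2 * insert_mean`).
#' @param min_support Minimum anchors per locus.
#' @param target_lengths Optional named vector; predicted intervals extending
#'   beyond a target are clamped and flagged.
#' @return list with `placements` (one row per locus: `contig_id`, `target`,
#'   `start`, `end`, `support`, `strand`, `clamped`, `classification`) and
#'   `classification` (one row per contig).
#' @export
cluster_placements <- function(pred, contig_ids, cluster_radius = 580L,
                               min_support = 2L, target_lengths = NULL) {
  plc <- NULL
  if (!is.null(pred) && nrow(pred) > 0 && is.null(pred$contig_end))
    pred$contig_end <- "FIVE_PRIME"   # degenerate input: treat as left-end
  for (cid in unique(pred$c_id)) {
    pc <- pred[pred$c_id == cid, , drop = FALSE]
    L <- pc$contig_len[1]
    for (tn in unique(pc$g_target)) {
      pt <- pc[pc$g_target == tn & pc$contig_end != "INTERNAL", , drop = FALSE]
      if (nrow(pt) == 0) next
      # which genome-side end of the placement does the anchor witness?
      left <- (pt$orientation == "+" & pt$contig_end == "FIVE_PRIME") |
        (pt$orientation == "-" & pt$contig_end == "THREE_PRIME")
      mk_clusters <- function(rows, side) {
        if (length(rows) == 0) return(list())
        lapply(single_linkage_1d(pt$pred_start[rows], cluster_radius),
               function(ix) {
                 mem <- rows[ix]
                 list(side = side,
                      start = as.integer(round(median(pt$pred_start[mem]))),
                      support = length(mem),
                      strand = names(sort(table(pt$orientation[mem]),
                                          decreasing = TRUE))[1])
               })
      }
      lcl <- mk_clusters(which(left), "left")
      rcl <- mk_clusters(which(!left), "right")
      used_r <- rep(FALSE, length(rcl))
      loci <- list()
      for (lc in lcl) {
        best <- NA_integer_
        for (j in seq_along(rcl)) {
          if (used_r[j] || rcl[[j]]$strand != lc$strand) next
          d <- rcl[[j]]$start - lc$start   # ref span - contig length
          if (d < -L - cluster_radius || d > cluster_radius) next
          if (is.na(best) || rcl[[j]]$support > rcl[[best]]$support ||
              (rcl[[j]]$support == rcl[[best]]$support &&
                 abs(d) < abs(rcl[[best]]$start - lc$start)))
            best <- j
        }
        if (!is.na(best)) {
          used_r[best] <- TRUE
          rc <- rcl[[best]]
          loci[[length(loci) + 1]] <- list(
            start = lc$start, end = max(lc$start + 1L, rc$start + L),
            support = lc$support + rc$support, strand = lc$strand)
        } else {
          loci[[length(loci) + 1]] <- list(
            start = lc$start, end = lc$start + L,
            support = lc$support, strand = lc$strand)
        }
      }
      for (j in seq_along(rcl)) {
        if (used_r[j]) next
        rc <- rcl[[j]]
        loci[[length(loci) + 1]] <- list(start = rc$start, end = rc$start + L,
                                         support = rc$support,
                                         strand = rc$strand)
      }
      for (lo in loci) {
        if (lo$support < min_support) next
        s <- lo$start; e <- lo$end
        clamped <- FALSE
        if (!is.null(target_lengths)) {
          TL <- target_lengths[[tn]]
          if (s < 0 || e > TL) {
            clamped <- TRUE
            s <- max(0L, s); e <- min(as.integer(TL), e)
          }
        } else if (s < 0) { clamped <- TRUE; s <- 0L }
        plc <- rbind(plc, data.frame(contig_id = cid, target = tn,
                                     start = s, end = e,
                                     support = lo$support, strand = lo$strand,
                                     clamped = clamped,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  n_loci <- setNames(rep(0L, length(contig_ids)), contig_ids)
  if (!is.null(plc)) {
    tab <- table(plc$contig_id)
    n_loci[names(tab)] <- as.integer(tab)
  }
  cls <- ifelse(n_loci == 0, "UNPLACED",
                ifelse(n_loci == 1, "SINGLE",
                       ifelse(n_loci == 2, "TWO", "MULTI")))
  classification <- data.frame(contig_id = contig_ids,
                               n_loci = unname(n_loci),
                               classification = unname(cls),
                               stringsAsFactors = FALSE)
  if (is.null(plc))
    plc <- data.frame(contig_id = character(0), target = character(0),
                      start = integer(0), end = integer(0),
                      support = integer(0), strand = character(0),
                      clamped = logical(0), stringsAsFactors = FALSE)
  plc$classification <- classification$classification[
    match(plc$contig_id, classification$contig_id)]
  plc$verified <- rep(NA, nrow(plc))
  rownames(plc) <- NULL
  list(placements = plc, classification = classification)
}

#' Verify placements by local realignment
#'
#' For each placement of the requested classes, the contig is locally aligned
#' against the reference window `locus +/- pad`. The placement is verified
#' when a qualifying local alignment (novel-insertion contigs match only at
#' their junction-spanning flanks, which suffices) overlaps the predicted
#' interval. Windows falling outside the reference leave the placement
#' unverified and flagged.
#'
#' @param placements Placement table from [cluster_placements()].
#' @param contigs data.frame with `contig_id`, `sequence`.
#' @param reference Named character vector of reference sequences.
#' @param pad Window padding (default `2 * insert_mean`).
#' @param min_score,min_identity Qualifying-alignment thresholds.
#' @param classes Which classifications to verify (default `SINGLE`).
#' @return `placements` with the `verified` column filled for the requested
#'   classes (TRUE/FALSE; others stay `NA`).
#' @export
verify_placements <- function(placements, contigs, reference, pad = 580L,
                              min_score = 30L, min_identity = 0.9,
                              classes = "SINGLE") {
  if (nrow(placements) == 0) return(placements)
  seqs <- setNames(contigs$sequence, contigs$contig_id)
  for (i in seq_len(nrow(placements))) {
    p <- placements[i, ]
    if (!(p$classification %in% classes)) next
    if (!(p$target %in% names(reference))) {
      placements$verified[i] <- FALSE
      next
    }
    L <- nchar(reference[[p$target]])
    ws <- max(0L, p$start - pad)
    we <- min(L, p$end + pad)
    if (ws >= we) { placements$verified[i] <- FALSE; next }
    win <- substr(reference[[p$target]], ws + 1L, we)
    q <- seqs[[p$contig_id]]
    if (p$strand == "-") q <- as.character(cpp_revcomp(q))
    hits <- align_local(q, win, min_score = min_score, max_hits = 4L)
    ok <- FALSE
    if (nrow(hits) > 0) {
      hs <- ws + hits$tstart
      he <- ws + hits$tend
      ok <- any(hits$identity >= min_identity &
                  hs < p$end & he > p$start)
    }
    placements$verified[i] <- ok
  }
  placements
}

#' Table-2-style placement summary
#'
#' @param classification Per-contig classification from
#'   [cluster_placements()].
#' @param n_total Total contigs entering placement.
#' @param n_predicted Contigs with at least one anchor before quality
#'   filtering.
#' @return One-row data.frame: total, predicted, high-quality, single, two,
#'   multi.
#' @export
placement_summary <- function(classification, n_total = nrow(classification),
                              n_predicted = NA_integer_) {
  data.frame(total_contigs = n_total,
             predicted = n_predicted,
             high_quality = sum(classification$classification != "UNPLACED"),
             single = sum(classification$classification == "SINGLE"),
             two = sum(classification$classification == "TWO"),
             multi = sum(classification$classification == "MULTI"))
}
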