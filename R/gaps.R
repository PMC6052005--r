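## Gap accounting: find N-run assembly gaps, intersect placed contigs with
## them, classify genic gaps against gene models, cross-reference with BAC
## placements, and aggregate a closure report.

#' Find assembly gaps (maximal N-runs)
#'
#' @param sequences Named character vector of reference sequences.
#' @return data.frame with `target`, `start`, `end` (0-based half-open),
#'   `gap_id`.
#' @export
find_gaps <- function(sequences) {
  out <- NULL
  for (tn in names(sequences)) {
    m <- gregexpr("[Nn]+", sequences[[tn]])[[1]]
    if (m[1] == -1) next
    st <- as.integer(m) - 1L
    out <- rbind(out, data.frame(target = tn, start = st,
                                 end = st + attr(m, "match.length"),
                                 stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(target = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  out$gap_id <- sprintf("gap%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

check_intervals <- function(df, what) {
  bad <- which(is.na(df$start) | is.na(df$end) | df$end < df$start)
  if (length(bad) > 0)
    stop("malformed ", what, " interval at row ", bad[1])
  invisible(df)
}

#' Intersect placed contigs with assembly gaps
#'
#' A contig is a gap contig when its placed interval overlaps a gap by at
#' least 1 bp. Per gap, `filled_bp` is the length of the gap covered by the
#' union of overlapping contig intervals; a gap is closed when that union
#' covers it entirely (so two partially overlapping contigs can jointly
#' close a gap).
#'
#' @param placements Placement table (`contig_id`, `target`, `start`, `end`).
#' @param gaps Gap table from [find_gaps()] or a BED file read with
#'   [read_bed()].
#' @return list with `assignments` (one row per contig-gap overlap:
#'   `contig_id`, `gap_id`, `overlap_bp`) and `per_gap` (per-gap summary:
#'   `gap_id`, `target`, `start`, `end`, `n_contigs`, `filled_bp`, `closed`).
#' @export
intersect_gaps <- function(placements, gaps) {
  check_intervals(placements, "placement")
  check_intervals(gaps, "gap")
  per_gap <- data.frame(gap_id = gaps$gap_id, target = gaps$target,
                        start = gaps$start, end = gaps$end,
                        n_contigs = 0L, filled_bp = 0L, closed = FALSE,
                        stringsAsFactors = FALSE)
  assignments <- data.frame(contig_id = character(0), gap_id = character(0),
                            overlap_bp = integer(0), stringsAsFactors = FALSE)
  if (nrow(placements) > 0 && nrow(gaps) > 0) {
    pg <- intervals_to_granges(placements)
    gg <- intervals_to_granges(gaps)
    ov <- GenomicRanges::findOverlaps(pg, gg)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    if (length(qh) > 0) {
      inter_w <- IRanges::width(IRanges::pintersect(IRanges::ranges(pg)[qh],
                                                    IRanges::ranges(gg)[sh]))
      assignments <- data.frame(contig_id = placements$contig_id[qh],
                                gap_id = gaps$gap_id[sh],
                                overlap_bp = inter_w,
                                stringsAsFactors = FALSE)
      for (gi in unique(sh)) {
        sel <- sh == gi
        pieces <- IRanges::pintersect(IRanges::ranges(pg)[qh[sel]],
                                      rep(IRanges::ranges(gg)[gi], sum(sel)))
        covered <- sum(IRanges::width(IRanges::reduce(pieces)))
        per_gap$n_contigs[gi] <- sum(sel)
        per_gap$filled_bp[gi] <- covered
        per_gap$closed[gi] <- covered == (gaps$end[gi] - gaps$start[gi])
      }
    }
  }
  list(assignments = assignments, per_gap = per_gap)
}

#' Derive 2 bp splice-site windows from intron features
#' @param features Feature table containing `intron` rows.
#' @return Feature table of `splice_site` rows (donor and acceptor ends).
#' @export
splice_sites <- function(features) {
  introns <- features[features$type == "intron", , drop = FALSE]
  if (nrow(introns) == 0)
    return(features[0, , drop = FALSE])
  out <- rbind(
    transform(introns, end = start + 2L, type = "splice_site"),
    transform(introns, start = end - 2L, type = "splice_site"))
  out[order(out$target, out$start), , drop = FALSE]
}

GENIC_CLASSES <- c("exon", "splice_site", "five_prime_UTR",
                   "three_prime_UTR", "intron", "ncRNA")

#' Classify gaps against gene models
#'
#' Each gap is labeled with every feature class it overlaps: exon, splice
#' site (2 bp windows at intron ends, derived automatically when absent),
#' UTR5/UTR3, intron, ncRNA. A gap overlapping at least one class is genic.
#'
#' @param gaps Gap table.
#' @param features Feature table (GFF3-style types).
#' @return data.frame: `gap_id`, one logical column per class, `genic`, and
#'   `classes` (comma-joined labels).
#' @export
classify_genic <- function(gaps, features) {
  known <- features$type %in% GENIC_CLASSES
  if (any(!known)) {
    extra <- setdiff(unique(features$type[!known]), character(0))
    warning("ignoring unknown feature type(s): ", paste(extra, collapse = ", "))
    features <- features[known, , drop = FALSE]
  }
  if (!any(features$type == "splice_site"))
    features <- rbind(features, splice_sites(features))
  out <- data.frame(gap_id = gaps$gap_id, stringsAsFactors = FALSE)
  for (cl in GENIC_CLASSES) out[[cl]] <- FALSE
  if (nrow(gaps) > 0 && nrow(features) > 0) {
    gg <- intervals_to_granges(gaps)
    fg <- intervals_to_granges(features)
    ov <- GenomicRanges::findOverlaps(gg, fg)
    for (h in seq_along(S4Vectors::queryHits(ov))) {
      gi <- S4Vectors::queryHits(ov)[h]
      cl <- features$type[S4Vectors::subjectHits(ov)[h]]
      out[gi, cl] <- TRUE
    }
  }
  m <- as.matrix(out[, GENIC_CLASSES, drop = FALSE])
  out$genic <- rowSums(m) > 0
  out$classes <- apply(m, 1, function(r)
    paste(GENIC_CLASSES[r], collapse = ","))
  out
}

#' Cross-reference gap contigs with BAC-insert placements
#'
#' A gap contig is BAC-covered when its placed interval overlaps any BAC
#' interval; the remainder are the novel-no-BAC set, reported with the gaps
#' they span.
#'
#' @param placements Placement table restricted to gap contigs.
#' @param assignments Contig-gap assignments from [intersect_gaps()].
#' @param bacs BAC interval table (`target`, `start`, `end`), or `NULL`.
#' @return list with `bac_covered` (named logical per contig),
#'   `novel_no_bac_contigs` and `novel_no_bac_gaps` (character vectors).
#' @export
bac_crossref <- function(placements, assignments, bacs = NULL) {
  ids <- unique(placements$contig_id)
  covered <- setNames(rep(FALSE, length(ids)), ids)
  if (is.null(bacs) || nrow(bacs) == 0) {
    if (length(ids) > 0)
      warning("no BAC placements supplied: all gap contigs counted novel-no-BAC")
  } else if (nrow(placements) > 0) {
    ov <- GenomicRanges::findOverlaps(intervals_to_granges(placements),
                                      intervals_to_granges(bacs))
    covered[unique(placements$contig_id[S4Vectors::queryHits(ov)])] <- TRUE
  }
  no_bac <- names(covered)[!covered]
  list(bac_covered = covered,
       novel_no_bac_contigs = no_bac,
       novel_no_bac_gaps = sort(unique(
         assignments$gap_id[assignments$contig_id %in% no_bac])))
}

#' Build the gap-closure report
#'
#' Combines gap intersection, genic classification and BAC cross-reference
#' into per-gap rows and aggregate counts.
#'
#' @param placements Placement table (typically verified SINGLE loci).
#' @param gaps Gap table.
#' @param features Optional gene-model feature table.
#' @param bacs Optional BAC interval table.
#' @return An object of class `gap_closure_report`: list with `per_gap`,
#'   `assignments`, `genic`, `bac`, and `aggregate` (named list:
#'   `n_gap_contigs`, `n_gaps_hit`, `n_gaps_closed`, `total_filled_bp`,
#'   `n_genic_gaps_hit`, `n_genic_gap_contigs`, `n_novel_no_bac`).
#' @export
gap_closure_report <- function(placements, gaps, features = NULL,
                               bacs = NULL) {
  ig <- intersect_gaps(placements, gaps)
  gap_contigs <- unique(ig$assignments$contig_id)
  genic <- if (!is.null(features) && nrow(features) > 0)
    classify_genic(gaps, features) else NULL
  per_gap <- ig$per_gap
  if (!is.null(genic)) {
    per_gap$genic <- genic$genic[match(per_gap$gap_id, genic$gap_id)]
    per_gap$classes <- genic$classes[match(per_gap$gap_id, genic$gap_id)]
  } else {
    per_gap$genic <- NA
    per_gap$classes <- NA_character_
  }
  gp <- placements[placements$contig_id %in% gap_contigs, , drop = FALSE]
  bac <- bac_crossref(gp, ig$assignments, bacs)
  genic_gaps <- if (!is.null(genic)) genic$gap_id[genic$genic] else character(0)
  n_genic_ctg <- length(unique(
    ig$assignments$contig_id[ig$assignments$gap_id %in% genic_gaps]))
  agg <- list(
    n_gap_contigs = length(gap_contigs),
    n_gaps_hit = sum(per_gap$n_contigs > 0),
    n_gaps_closed = sum(per_gap$closed),
    total_filled_bp = sum(per_gap$filled_bp),
    n_genic_gaps_hit = sum(per_gap$n_contigs > 0 &
                             per_gap$gap_id %in% genic_gaps),
    n_genic_gap_contigs = n_genic_ctg,
    n_novel_no_bac = length(bac$novel_no_bac_contigs))
  structure(list(per_gap = per_gap, assignments = ig$assignments,
                 genic = genic, bac = bac, aggregate = agg),
            class = "gap_closure_report")
}

#' @export
print.gap_closure_report <- function(x, ...) {
  a <- x$aggregate
  cat("Gap closure report\n")
  cat("  gap contigs:        ", a$n_gap_contigs, "\n")
  cat("  gaps hit / closed:  ", a$n_gaps_hit, "/", a$n_gaps_closed, "\n")
  cat("  bases filled:       ", a$total_filled_bp, "\n")
  cat("  genic gaps hit:     ", a$n_genic_gaps_hit,
      " (", a$n_genic_gap_contigs, " contigs)\n", sep = "")
  cat("  novel-no-BAC contigs:", a$n_novel_no_bac, "\n")
  invisible(x)
}
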