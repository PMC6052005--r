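## Two-tier pseudo-de novo assembly: greedy overlap-layout-consensus per
## sample (primary), then pooled re-assembly per group with singlet exclusion
## (secondary).

#' Greedy overlap-layout-consensus assembly
#'
#' Repeatedly merges the pair of sequences with the longest qualifying
#' overlap (shared-kmer diagonal seeds verified by mismatch-tolerant
#' comparison, both orientations), building a per-column majority consensus
#' with quality-weighted tie-breaks, until no overlap of at least
#' `min_overlap` bp at `min_identity` remains. Deterministic: ties are broken
#' lexicographically by sequence id.
#'
#' @param seqs Character vector of reads or contigs (named, or `ids` given).
#' @param quals Optional parallel phred+33 quality strings (consensus
#'   weights); `NULL` weights every base equally.
#' @param ids Sequence ids (default names of `seqs`).
#' @param min_overlap Minimum overlap length in bp.
#' @param min_identity Minimum overlap identity.
#' @param k Seed k-mer length for overlap candidates.
#' @param id_prefix Prefix for output contig ids.
#' @return data.frame with `contig_id`, `sequence`, `n_reads`; attribute
#'   `members` maps every input id to its contig (`contig_id`, `read_id`,
#'   `offset`, `rc`).
#' @export
assemble_greedy <- function(seqs, quals = NULL, ids = names(seqs),
                            min_overlap = 40L, min_identity = 0.97,
                            k = 15L, id_prefix = "ctg") {
  if (length(seqs) == 0) {
    out <- data.frame(contig_id = character(0), sequence = character(0),
                      n_reads = integer(0), stringsAsFactors = FALSE)
    attr(out, "members") <- data.frame(contig_id = character(0),
                                       read_id = character(0),
                                       offset = integer(0), rc = logical(0),
                                       stringsAsFactors = FALSE)
    return(out)
  }
  if (is.null(ids)) ids <- sprintf("r%06d", seq_along(seqs))
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  if (is.null(quals)) quals <- rep(NA_character_, length(seqs))
  if (min_overlap < 20) stop("min_overlap must be at least 20")
  res <- cpp_assemble_greedy(ids, unname(seqs), unname(quals),
                             as.integer(min_overlap), min_identity,
                             as.integer(k), 4L, 1000L)
  n <- length(res$sequence)
  cid <- sprintf("%s%05d", id_prefix, seq_len(n))
  out <- data.frame(contig_id = cid, sequence = res$sequence,
                    n_reads = res$n_reads, stringsAsFactors = FALSE)
  mem <- res$members
  attr(out, "members") <- data.frame(contig_id = cid[mem$contig],
                                     read_id = ids[mem$read],
                                     offset = mem$offset, rc = mem$rc,
                                     stringsAsFactors = FALSE)
  out
}

#' Secondary (pooled) assembly with singlet exclusion
#'
#' Pools the primary contigs of all samples in a group and re-assembles them
#' with a larger overlap requirement. A secondary contig supported by exactly
#' one primary contig (necessarily from one sample) is a singlet: it is
#' binned as debris and excluded. Each surviving contig records the union of
#' contributing samples.
#'
#' @param primary Named list (by sample) of primary-assembly data.frames from
#'   [assemble_greedy()].
#' @param min_overlap Minimum contig-merge overlap in bp.
#' @param min_identity Minimum overlap identity.
#' @param min_length Optional minimum secondary-contig length (0 disables).
#' @param id_prefix Prefix for secondary contig ids.
#' @return list with `contigs` (data.frame: `contig_id`, `sequence`,
#'   `n_primary`, `n_samples`, `sample_ids` comma-joined) and `debris`
#'   (excluded singlets, same columns).
#' @export
secondary_assembly <- function(primary, min_overlap = 100L,
                               min_identity = 0.97, min_length = 0L,
                               id_prefix = "sec") {
  stopifnot(is.list(primary), length(primary) >= 1)
  if (is.null(names(primary)))
    names(primary) <- sprintf("S%02d", seq_along(primary))
  pooled_seq <- character(0)
  pooled_sample <- character(0)
  for (s in names(primary)) {
    p <- primary[[s]]
    if (nrow(p) == 0) next
    ids <- paste0(s, ".", p$contig_id)
    pooled_seq <- c(pooled_seq, setNames(p$sequence, ids))
    pooled_sample <- c(pooled_sample, setNames(rep(s, nrow(p)), ids))
  }
  empty <- data.frame(contig_id = character(0), sequence = character(0),
                      n_primary = integer(0), n_samples = integer(0),
                      sample_ids = character(0), stringsAsFactors = FALSE)
  if (length(pooled_seq) == 0) return(list(contigs = empty, debris = empty))
  asm <- assemble_greedy(pooled_seq, min_overlap = min_overlap,
                         min_identity = min_identity, id_prefix = id_prefix)
  mem <- attr(asm, "members")
  info <- do.call(rbind, lapply(seq_len(nrow(asm)), function(i) {
    m <- mem[mem$contig_id == asm$contig_id[i], , drop = FALSE]
    ss <- sort(unique(pooled_sample[m$read_id]))
    data.frame(n_primary = nrow(m), n_samples = length(ss),
               sample_ids = paste(ss, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- cbind(asm[, c("contig_id", "sequence")], info)
  singlet <- out$n_primary == 1
  short <- min_length > 0 & nchar(out$sequence) < min_length
  keep <- !singlet & !short
  contigs <- out[keep, , drop = FALSE]
  rownames(contigs) <- NULL
  debris <- out[!keep, , drop = FALSE]
  rownames(debris) <- NULL
  attr(contigs, "members") <- mem[mem$contig_id %in% contigs$contig_id, ,
                                  drop = FALSE]
  list(contigs = contigs, debris = debris)
}

#' Assembly summary statistics
#'
#' N50 is the largest length L such that contigs of length >= L sum to at
#' least half the total assembled bases.
#'
#' @param x Contig data.frame (with `sequence`) or a numeric vector of
#'   contig lengths.
#' @return list with `n_contigs`, `total_bp`, `largest_bp`, `n50_bp`.
#' @export
assembly_stats <- function(x) {
  lens <- if (is.numeric(x)) as.numeric(x) else nchar(x$sequence)
  if (length(lens) == 0)
    return(list(n_contigs = 0L, total_bp = 0, largest_bp = 0, n50_bp = 0))
  lens <- sort(lens, decreasing = TRUE)
  total <- sum(lens)
  n50 <- lens[which(cumsum(lens) >= total / 2)[1]]
  list(n_contigs = length(lens), total_bp = total, largest_bp = lens[1],
       n50_bp = n50)
}
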