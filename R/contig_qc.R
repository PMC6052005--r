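## Per-contig quality metrics: GC content, DUST and entropy complexity on a
## 0-100 scale computed from overlapping triplet counts, exact-duplicate
## removal, and an optional contaminant k-mer screen.

#' GC content (percent)
#'
#' `100 * (G + C) / (A + C + G + T)`; N and other ambiguity codes are
#' excluded from numerator and denominator. All-N sequences yield `NA`.
#'
#' @param seqs Character vector of sequences.
#' @return Numeric vector of percentages.
#' @export
gc_content <- function(seqs) {
  x <- Biostrings::DNAStringSet(seqs)
  f <- Biostrings::letterFrequency(x, c("A", "C", "G", "T"))
  acgt <- rowSums(f)
  out <- ifelse(acgt > 0, 100 * (f[, "C"] + f[, "G"]) / acgt, NA_real_)
  if (anyNA(out)) warning("GC content undefined for sequence(s) without ACGT bases")
  unname(out)
}

triplet_counts <- function(seq) {
  L <- nchar(seq)
  if (L < 3) return(integer(0))
  tri <- substring(seq, 1:(L - 2), 3:L)
  tri <- tri[!grepl("[^ACGT]", tri)]
  if (length(tri) == 0) return(integer(0))
  table(tri)
}

#' DUST low-complexity score (0-100)
#'
#' Over all overlapping triplets (triplets containing N skipped), with
#' `c_t` the count of triplet `t` and `k` the number of counted triplets:
#' `100 * sum(c_t * (c_t - 1) / 2) / (k * (k - 1) / 2)`. Higher means lower
#' complexity; a homopolymer scores 100, a sequence whose triplets are all
#' distinct scores 0. Sequences shorter than 3 bp yield `NA`.
#'
#' @param seqs Character vector of sequences.
#' @return Numeric vector of scores.
#' @export
dust_score <- function(seqs) {
  vapply(seqs, function(s) {
    ct <- triplet_counts(s)
    k <- sum(ct)
    if (k < 1) return(NA_real_)
    if (k < 2) return(0)
    min(100, max(0, 100 * sum(ct * (ct - 1) / 2) / (k * (k - 1) / 2)))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Triplet entropy score (0-100)
#'
#' With `p_t = c_t / k` over observed triplets:
#' `100 * (-sum(p_t * ln(p_t))) / ln(min(k, 64))`. Higher means higher
#' complexity; 0 for a homopolymer, 100 when all observed triplets are
#' equally frequent and distinct (k <= 64). Sequences shorter than 3 bp
#' yield `NA`.
#'
#' @param seqs Character vector of sequences.
#' @return Numeric vector of scores.
#' @export
entropy_score <- function(seqs) {
  vapply(seqs, function(s) {
    ct <- triplet_counts(s)
    k <- sum(ct)
    if (k < 1) return(NA_real_)
    if (k < 2) return(0)
    p <- ct / k
    min(100, max(0, 100 * (-sum(p * log(p))) / log(min(k, 64))))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Remove exact duplicate contigs
#'
#' Exact sequence duplicates, including reverse-complement duplicates, are
#' collapsed to a single representative: the lexicographically smallest id,
#' so the outcome is independent of input order.
#'
#' @param contigs data.frame with `contig_id` and `sequence`.
#' @return list with `contigs` (deduplicated) and `removed` (`contig_id`,
#'   `duplicate_of`).
#' @export
dedup_contigs <- function(contigs) {
  if (nrow(contigs) == 0)
    return(list(contigs = contigs,
                removed = data.frame(contig_id = character(0),
                                     duplicate_of = character(0),
                                     stringsAsFactors = FALSE)))
  rc <- as.character(cpp_revcomp(contigs$sequence))
  key <- pmin(contigs$sequence, rc)
  keep_id <- tapply(contigs$contig_id, key, function(ids) min(ids))
  keeper <- keep_id[key]
  removed_sel <- contigs$contig_id != keeper
  list(contigs = contigs[!removed_sel, , drop = FALSE],
       removed = data.frame(contig_id = contigs$contig_id[removed_sel],
                            duplicate_of = unname(keeper[removed_sel]),
                            stringsAsFactors = FALSE))
}

#' Build a contaminant k-mer set from sequences
#'
#' @param seqs Contaminant sequences.
#' @param k k-mer length.
#' @return Character vector of k-mers (both strands).
#' @export
kmer_set <- function(seqs, k = 31L) {
  out <- character(0)
  for (s in c(seqs, as.character(cpp_revcomp(seqs)))) {
    L <- nchar(s)
    if (L < k) next
    km <- substring(s, 1:(L - k + 1), k:L)
    out <- c(out, km[!grepl("[^ACGT]", km)])
  }
  unique(out)
}

#' Screen contigs against a contaminant k-mer set
#'
#' A contig is flagged when at least `min_fraction` of its k-mers occur in
#' the contaminant set.
#'
#' @param contigs data.frame with `contig_id` and `sequence`.
#' @param contaminant_kmers Character vector from [kmer_set()].
#' @param k k-mer length (must match the set construction).
#' @param min_fraction Flagging threshold.
#' @return Logical vector, one flag per contig.
#' @export
contaminant_screen <- function(contigs, contaminant_kmers, k = 31L,
                               min_fraction = 0.5) {
  if (length(contaminant_kmers) == 0) {
    warning("empty contaminant k-mer set: all contigs pass")
    return(rep(FALSE, nrow(contigs)))
  }
  vapply(contigs$sequence, function(s) {
    L <- nchar(s)
    if (L < k) return(FALSE)
    km <- substring(s, 1:(L - k + 1), k:L)
    mean(km %in% contaminant_kmers) >= min_fraction
  }, logical(1), USE.NAMES = FALSE)
}

#' Per-contig QC table
#'
#' GC, DUST and entropy scores plus duplicate and (optional) contaminant
#' flags. Contigs are additionally flagged `low_complexity` when DUST > 7 or
#' entropy < 70 — the conventional report-only thresholds; filtering on them
#' is the caller's decision.
#'
#' @param contigs data.frame with `contig_id` and `sequence`.
#' @param contaminant_kmers Optional k-mer set for [contaminant_screen()].
#' @param k Contaminant k-mer length.
#' @param dust_flag,entropy_flag Report-only complexity thresholds.
#' @return data.frame with one QC row per contig.
#' @export
contig_qc <- function(contigs, contaminant_kmers = NULL, k = 31L,
                      dust_flag = 7, entropy_flag = 70) {
  dd <- dedup_contigs(contigs)
  dup_of <- setNames(rep(NA_character_, nrow(contigs)), contigs$contig_id)
  dup_of[dd$removed$contig_id] <- dd$removed$duplicate_of
  contam <- if (is.null(contaminant_kmers)) rep(FALSE, nrow(contigs))
  else contaminant_screen(contigs, contaminant_kmers, k)
  dust <- dust_score(contigs$sequence)
  ent <- entropy_score(contigs$sequence)
  data.frame(contig_id = contigs$contig_id,
             length = nchar(contigs$sequence),
             gc = gc_content(contigs$sequence),
             dust = dust, entropy = ent,
             low_complexity = !is.na(dust) & !is.na(ent) &
               (dust > dust_flag | ent < entropy_flag),
             duplicate_of = unname(dup_of),
             contaminant = contam,
             stringsAsFactors = FALSE)
}
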