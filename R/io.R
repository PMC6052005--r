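## File I/O. Sequences travel through the package as named character vectors
## (uppercase DNA); all internal intervals are 0-based half-open. Conversions
## to the 1-based conventions of GRanges/GFF3/SAM happen here and nowhere else.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA (60-column wrapped)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param desc Optional character vector of description lines appended to ids.
#' @export
write_fasta <- function(seqs, path, desc = NULL) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- if (is.null(desc)) names(seqs) else paste(names(seqs), desc)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path Path to a FASTQ file (phred+33).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = sub("\\s.*$", "", names(x)),
             seq = toupper(as.character(x)),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a FASTQ file (phred+33)
#'
#' @param ids,seqs,quals Parallel character vectors.
#' @param path Output path.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Read mate FASTQ files into a paired-read table
#'
#' @param path1,path2 Paths to the mate-1 and mate-2 FASTQ files.
#' @return data.frame with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_paired_fastq <- function(path1, path2) {
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  if (nrow(r1) != nrow(r2) || !all(r1$id == r2$id))
    stop("mate files do not pair up read-for-read")
  data.frame(id = r1$id, seq1 = r1$seq, qual1 = r1$qual,
             seq2 = r2$seq, qual2 = r2$qual, stringsAsFactors = FALSE)
}

#' Write a paired-read table to two FASTQ files
#'
#' @param reads Paired-read data.frame (see [read_paired_fastq()]).
#' @param path1,path2 Output paths for mate 1 and mate 2.
#' @export
write_paired_fastq <- function(reads, path1, path2) {
  write_fastq(reads$id, reads$seq1, reads$qual1, path1)
  write_fastq(reads$id, reads$seq2, reads$qual2, path2)
  invisible(c(path1, path2))
}

## ---- intervals ------------------------------------------------------------

#' Convert a 0-based half-open interval table to GRanges
#' @param df data.frame with columns `target`, `start`, `end` (0-based half-open).
#' @return A `GRanges` (1-based closed).
#' @export
intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(df$target,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Read a BED file into a 0-based half-open interval table
#' @param path Path to a BED file.
#' @return data.frame with columns `target`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- data.frame(target = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$name)) df$name <- as.character(mc$name)
  if (!is.null(mc$score)) df$score <- as.numeric(mc$score)
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st != "*")) df$strand <- st
  df
}

#' Write a 0-based half-open interval table to BED
#' @param df data.frame with `target`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  gr <- intervals_to_granges(df)
  if (!is.null(df$name)) S4Vectors::mcols(gr)$name <- df$name
  if (!is.null(df$score)) S4Vectors::mcols(gr)$score <- df$score
  if (!is.null(df$strand)) GenomicRanges::strand(gr) <- df$strand
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write gene models as BED12
#'
#' One row per gene; exon blocks from the feature table. Intended for gene
#' models produced by [build_reference()].
#' @param features Feature table (`target`, `start`, `end`, `type`, `gene_id`,
#'   `strand`).
#' @param path Output path.
#' @export
write_bed12 <- function(features, path) {
  lines <- character(0)
  for (g in unique(features$gene_id)) {
    f <- features[features$gene_id == g, , drop = FALSE]
    blocks <- f[f$type %in% c("exon", "ncRNA"), , drop = FALSE]
    blocks <- blocks[order(blocks$start), , drop = FALSE]
    gstart <- min(f$start); gend <- max(f$end)
    lines <- c(lines, paste(
      f$target[1], gstart, gend, g, 0L, f$strand[1], gstart, gend, "0,0,0",
      nrow(blocks),
      paste0(paste(blocks$end - blocks$start, collapse = ","), ","),
      paste0(paste(blocks$start - gstart, collapse = ","), ","),
      sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a feature table as GFF3
#' @param features data.frame with `target`, `start`, `end` (0-based
#'   half-open), `type`, `gene_id`, `strand`.
#' @param path Output path.
#' @export
write_gff3 <- function(features, path) {
  gr <- intervals_to_granges(features)
  S4Vectors::mcols(gr)$type <- features$type
  S4Vectors::mcols(gr)$ID <- paste0(features$gene_id, ":", features$type, ":",
                                    seq_len(nrow(features)))
  S4Vectors::mcols(gr)$gene_id <- features$gene_id
  S4Vectors::mcols(gr)$source <- "gapfillr"
  GenomicRanges::strand(gr) <- features$strand
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 feature file into a 0-based half-open feature table
#' @param path Path to a GFF3 file.
#' @return data.frame with `target`, `start`, `end`, `type`, `gene_id`, `strand`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  gene <- if (!is.null(mc$gene_id)) as.character(mc$gene_id) else
    as.character(mc$ID)
  data.frame(target = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             type = as.character(mc$type),
             gene_id = gene,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

## ---- SAM subset -----------------------------------------------------------
## Only the 11 mandatory columns are read or written. Internal `pos` stays
## 0-based; the +1/-1 happens below.

#' Write alignment records as a SAM file
#'
#' @param aln data.frame with columns `qname`, `flag`, `rname`, `pos`
#'   (0-based; ignored for unmapped records), `mapq`, `cigar`, `seq`, `qual`.
#'   Optional `rnext`, `pnext`, `tlen`.
#' @param targets Named integer vector of target lengths for the `@SQ` header.
#' @param path Output path.
#' @export
write_sam <- function(aln, targets, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(targets), as.integer(targets)))
  rname <- ifelse(is.na(aln$rname), "*", aln$rname)
  pos <- ifelse(is.na(aln$pos), 0L, aln$pos + 1L)
  mapq <- ifelse(is.na(aln$mapq), 0L, aln$mapq)
  cigar <- ifelse(is.na(aln$cigar) | aln$cigar == "", "*", aln$cigar)
  rnext <- if (is.null(aln$rnext)) "*" else ifelse(is.na(aln$rnext), "*", aln$rnext)
  pnext <- if (is.null(aln$pnext)) 0L else ifelse(is.na(aln$pnext), 0L, aln$pnext + 1L)
  tlen <- if (is.null(aln$tlen)) 0L else ifelse(is.na(aln$tlen), 0L, aln$tlen)
  body <- paste(aln$qname, aln$flag, rname, pos, mapq, cigar,
                rnext, pnext, tlen, aln$seq, aln$qual, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file (mandatory columns only)
#'
#' @param path Path to a SAM file.
#' @return list with `targets` (named lengths from `@SQ`) and `aln`
#'   (data.frame, `pos`/`pnext` 0-based, `NA` for unmapped).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  tn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  tl <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0) {
    aln <- data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE)
    return(list(targets = setNames(tl, tn), aln = aln))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2))
  rname <- get(3); rname[rname == "*"] <- NA
  pos <- as.integer(get(4)) - 1L; pos[is.na(rname)] <- NA
  aln <- data.frame(qname = get(1), flag = flag, rname = rname, pos = pos,
                    mapq = as.integer(get(5)), cigar = get(6),
                    rnext = get(7), pnext = as.integer(get(8)) - 1L,
                    tlen = as.integer(get(9)), seq = get(10), qual = get(11),
                    stringsAsFactors = FALSE)
  list(targets = setNames(tl, tn), aln = aln)
}

## ---- truth table ----------------------------------------------------------

#' Write the simulation truth table
#' @param truth Truth data.frame from [build_donor()].
#' @param path Output path (TSV with header).
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a simulation truth table
#' @param path Path to a truth TSV.
#' @return data.frame of truth records.
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
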