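# Independent brute-force oracles. These deliberately avoid the package's own
# code paths: character-level scans, direct formula evaluation, per-base
# interval membership.

oracle_revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# maximal N-runs by run-length encoding of the character vector
oracle_nruns <- function(s) {
  ch <- strsplit(s, "")[[1]]
  r <- rle(ch %in% c("N", "n"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# N50 by scanning every candidate length
oracle_n50 <- function(lens) {
  if (length(lens) == 0) return(0)
  total <- sum(lens)
  cand <- sort(unique(lens), decreasing = TRUE)
  for (L in cand) if (sum(lens[lens >= L]) >= total / 2) return(L)
  min(lens)
}

# triplet statistics by explicit dictionary
oracle_triplet_stats <- function(s) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  if (L < 3) return(list(dust = NA_real_, entropy = NA_real_))
  tri <- vapply(1:(L - 2), function(i) paste(ch[i:(i + 2)], collapse = ""),
                character(1))
  tri <- tri[vapply(tri, function(t)
    all(strsplit(t, "")[[1]] %in% c("A", "C", "G", "T")), logical(1))]
  k <- length(tri)
  if (k < 1) return(list(dust = NA_real_, entropy = NA_real_))
  if (k < 2) return(list(dust = 0, entropy = 0))
  counts <- table(tri)
  dust <- 100 * sum(counts * (counts - 1) / 2) / (k * (k - 1) / 2)
  p <- counts / k
  entropy <- 100 * (-sum(p * log(p))) / log(min(k, 64))
  list(dust = as.numeric(dust), entropy = as.numeric(entropy))
}

# GC by character counting
oracle_gc <- function(s) {
  ch <- strsplit(s, "")[[1]]
  acgt <- ch[ch %in% c("A", "C", "G", "T")]
  if (length(acgt) == 0) return(NA_real_)
  100 * mean(acgt %in% c("G", "C"))
}

# reconstruct the donor from reference + truth + snps, piecewise and purely
# by string surgery (independent of build_donor's internals)
oracle_reconstruct_donor <- function(reference, truth, snps) {
  out <- reference
  for (tn in names(reference)) {
    ch <- strsplit(reference[[tn]], "")[[1]]
    sn <- snps[snps$target == tn, , drop = FALSE]
    if (nrow(sn) > 0) ch[sn$pos + 1] <- sn$donor_base
    tt <- truth[truth$ref_target == tn, , drop = FALSE]
    gf <- tt[tt$kind == "gap_fill", , drop = FALSE]
    for (i in seq_len(nrow(gf)))
      ch[(gf$ref_start[i] + 1):gf$ref_end[i]] <-
        strsplit(gf$sequence[i], "")[[1]]
    ins <- tt[tt$kind == "nongap_insertion", , drop = FALSE]
    ins <- ins[order(-ins$ref_start), , drop = FALSE]  # right to left
    for (i in seq_len(nrow(ins))) {
      p <- ins$ref_start[i]
      ch <- c(ch[seq_len(p)], strsplit(ins$sequence[i], "")[[1]],
              if (p < length(ch)) ch[(p + 1):length(ch)])
    }
    out[[tn]] <- paste(ch, collapse = "")
  }
  out
}

# per-base membership oracle for interval overlap on small coordinates
oracle_overlap_bp <- function(s1, e1, s2, e2, limit = 20000L) {
  a <- rep(FALSE, limit); b <- rep(FALSE, limit)
  if (e1 > s1) a[(s1 + 1):e1] <- TRUE
  if (e2 > s2) b[(s2 + 1):e2] <- TRUE
  sum(a & b)
}

# Smith-Waterman score oracle via Biostrings (match +1, mismatch -1, gap -2
# as linear penalty: opening 0, extension 2)
oracle_sw_score <- function(query, target) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  as.numeric(Biostrings::pairwiseAlignment(
    query, target, type = "local", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2, scoreOnly = TRUE))
}

# small shared dataset for cross-module tests (simulated once per run)
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 3, genome_length = 3e5, n_gaps = 4,
                        gap_length_range = c(300, 500), n_novel_at_gap = 2,
                        n_novel_nongap = 2, novel_length_range = c(1000, 2000),
                        coverage = 10, base_error_rate = 0.002, n_genes = 8,
                        snp_rate = 5e-4)
      cache <<- simulate_dataset(cfg, n_samples = 2)
    }
    cache
  }
})

small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_pipeline(small_dataset(), verbose = FALSE)
    cache
  }
})
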