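## Synthetic study generator: a reference with N-run gaps and gene models, a
## donor genome carrying planted novel segments, and simulated paired-end
## reads with a known truth table. All coordinates 0-based half-open.

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic dataset: genome and gap
#' geometry, planted novel segments, the sequencing model (100 bp paired-end
#' reads, 290 bp inserts by default), and donor-vs-reference SNP rate.
#'
#' @param seed Integer seed; every random draw in the generator derives from it.
#' @param genome_length Total reference length in bp.
#' @param n_targets Number of chromosomes the length is split over.
#' @param n_gaps Number of N-run assembly gaps.
#' @param gap_length_range Length range (bp) for gaps.
#' @param n_novel_at_gap Number of gaps whose true sequence the donor carries
#'   (gap-fill novel segments).
#' @param n_novel_nongap Number of novel insertions at non-gap loci
#'   (population-specific sequence absent from the reference).
#' @param novel_length_range Length range (bp) for non-gap insertions.
#' @param read_length Read length in bp (>= 50).
#' @param insert_mean,insert_sd Fragment (insert) size model in bp.
#' @param coverage Fold sequencing coverage of the donor.
#' @param base_error_rate Per-base substitution error probability.
#' @param n_genes Number of gene models on the reference.
#' @param snp_rate Per-base donor-vs-reference SNP probability outside novel
#'   segments.
#' @param gc Base composition (GC fraction) of simulated sequence.
#' @param lowq_tail_frac Fraction of reads given a low-quality (phred 2) 3'
#'   tail of 5-15 bp, so the trimmer has work to do.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 2e6, n_targets = 1L,
                       n_gaps = 10L, gap_length_range = c(300L, 800L),
                       n_novel_at_gap = 5L, n_novel_nongap = 5L,
                       novel_length_range = c(500L, 5000L),
                       read_length = 100L, insert_mean = 290L, insert_sd = 30L,
                       coverage = 10, base_error_rate = 0.002,
                       n_genes = 30L, snp_rate = 5e-4,
                       gc = 0.41, lowq_tail_frac = 0.05) {
  stopifnot(read_length >= 50, insert_mean >= read_length,
            n_gaps >= 0, n_novel_at_gap >= 0, n_novel_nongap >= 0,
            n_genes >= 0, coverage >= 0,
            gap_length_range[1] <= gap_length_range[2],
            novel_length_range[1] <= novel_length_range[2],
            base_error_rate >= 0, base_error_rate < 1,
            snp_rate >= 0, snp_rate < 1)
  if (n_novel_at_gap > n_gaps)
    stop("n_novel_at_gap cannot exceed n_gaps")
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              n_targets = as.integer(n_targets), n_gaps = as.integer(n_gaps),
              gap_length_range = as.integer(gap_length_range),
              n_novel_at_gap = as.integer(n_novel_at_gap),
              n_novel_nongap = as.integer(n_novel_nongap),
              novel_length_range = as.integer(novel_length_range),
              read_length = as.integer(read_length),
              insert_mean = as.integer(insert_mean),
              insert_sd = as.numeric(insert_sd),
              coverage = coverage, base_error_rate = base_error_rate,
              n_genes = as.integer(n_genes), snp_rate = snp_rate,
              gc = gc, lowq_tail_frac = lowq_tail_frac)
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## draw non-overlapping intervals with a minimum separation; error when the
## space cannot accommodate them
place_intervals <- function(L, lens, min_sep, margin, forbid = NULL,
                            max_attempts = 500L, what = "interval") {
  placed <- data.frame(start = integer(0), end = integer(0))
  for (len in lens) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      s <- floor(runif(1, margin, L - margin - len + 1))
      e <- s + len
      clash <- FALSE
      if (nrow(placed) > 0)
        clash <- any(s < placed$end + min_sep & e > placed$start - min_sep)
      if (!clash && !is.null(forbid) && nrow(forbid) > 0)
        clash <- any(s < forbid$end + min_sep & e > forbid$start - min_sep)
      if (!clash) { placed <- rbind(placed, data.frame(start = s, end = e)); ok <- TRUE; break }
    }
    if (!ok) stop("infeasible configuration: cannot place ", what,
                  " of length ", len)
  }
  placed
}

build_gene <- function(target, start, gene_id, strand) {
  n_ex <- sample(2:5, 1)
  ex_len <- sample(150:400, n_ex, replace = TRUE)
  in_len <- sample(500:3000, n_ex - 1, replace = TRUE)
  utr5 <- sample(50:120, 1)
  utr3 <- sample(50:120, 1)
  rows <- list()
  pos <- start
  for (i in seq_len(n_ex)) {
    rows[[length(rows) + 1]] <- data.frame(target = target, start = pos,
                                           end = pos + ex_len[i], type = "exon",
                                           gene_id = gene_id, strand = strand)
    if (i < n_ex) {
      ipos <- pos + ex_len[i]
      rows[[length(rows) + 1]] <- data.frame(target = target, start = ipos,
                                             end = ipos + in_len[i],
                                             type = "intron",
                                             gene_id = gene_id, strand = strand)
      pos <- ipos + in_len[i]
    } else pos <- pos + ex_len[i]
  }
  gstart <- start; gend <- pos
  # UTRs at the transcript ends (left end is 5' for + genes)
  lutr <- data.frame(target = target, start = gstart, end = gstart + utr5,
                     type = if (strand == "+") "five_prime_UTR" else "three_prime_UTR",
                     gene_id = gene_id, strand = strand)
  rutr <- data.frame(target = target, start = gend - utr3, end = gend,
                     type = if (strand == "+") "three_prime_UTR" else "five_prime_UTR",
                     gene_id = gene_id, strand = strand)
  do.call(rbind, c(rows, list(lutr, rutr)))
}

#' Build the synthetic reference: sequence, N-run gaps, gene models
#'
#' Generates one or more chromosomes of random sequence, places
#' non-overlapping gene models (>= 2 exons with introns and UTRs, plus some
#' ncRNA genes), then carves N-run assembly gaps, roughly half inside gene
#' bodies (genic gaps) and half intergenic. Gaps keep at least
#' `2 * insert_mean` bp from sequence ends and from each other.
#'
#' @param config A [sim_config()].
#' @return list with `sequences` (named character), `gaps` (data.frame
#'   `target`, `start`, `end`, `gap_id`), `features` (gene-model table).
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  margin <- 2L * config$insert_mean
  tlen <- rep(floor(config$genome_length / config$n_targets), config$n_targets)
  names(tlen) <- paste0("chr", seq_len(config$n_targets))
  seqs <- vapply(tlen, random_dna, character(1), gc = config$gc)

  # distribute genes and gaps round-robin over targets
  gene_t <- rep(names(tlen), length.out = max(config$n_genes, 0))
  gap_t <- rep(names(tlen), length.out = max(config$n_gaps, 0))

  features <- NULL
  gaps <- NULL
  for (tn in names(tlen)) {
    L <- tlen[[tn]]
    ng <- sum(gene_t == tn)
    feats_t <- NULL
    gene_spans <- data.frame(start = integer(0), end = integer(0))
    if (ng > 0) {
      n_nc <- max(0L, round(0.15 * ng))
      kinds <- c(rep("coding", ng - n_nc), rep("ncRNA", n_nc))
      # draw structures first so placement knows the lengths
      glens <- integer(ng)
      protos <- vector("list", ng)
      for (i in seq_len(ng)) {
        gid <- sprintf("%s_gene%03d", tn, i)
        strand <- sample(c("+", "-"), 1)
        if (kinds[i] == "coding") {
          protos[[i]] <- build_gene(tn, 0L, gid, strand)
          glens[i] <- max(protos[[i]]$end)
        } else {
          len <- sample(300:2000, 1)
          protos[[i]] <- data.frame(target = tn, start = 0L, end = len,
                                    type = "ncRNA", gene_id = gid,
                                    strand = strand)
          glens[i] <- len
        }
      }
      gene_spans <- place_intervals(L, glens, min_sep = 1000L, margin = margin,
                                    what = "gene")
      for (i in seq_len(ng)) {
        f <- protos[[i]]
        f$start <- f$start + gene_spans$start[i]
        f$end <- f$end + gene_spans$start[i]
        feats_t <- rbind(feats_t, f)
      }
    }
    # gaps: alternate genic / intergenic placement
    ngap <- sum(gap_t == tn)
    if (ngap > 0) {
      glens <- sample(seq(config$gap_length_range[1], config$gap_length_range[2]),
                      ngap, replace = TRUE)
      placed <- data.frame(start = integer(0), end = integer(0))
      for (i in seq_len(ngap)) {
        want_genic <- (i %% 2 == 1) && nrow(gene_spans) > 0
        ok <- FALSE
        for (a in 1:500) {
          if (want_genic) {
            g <- gene_spans[sample(nrow(gene_spans), 1), ]
            if (g$end - g$start <= glens[i] + 2) next
            s <- floor(runif(1, g$start, g$end - glens[i]))
          } else {
            s <- floor(runif(1, margin, L - margin - glens[i] + 1))
            if (nrow(gene_spans) > 0 &&
                any(s < gene_spans$end & s + glens[i] > gene_spans$start)) next
          }
          e <- s + glens[i]
          if (s < margin || e > L - margin) next
          if (nrow(placed) > 0 &&
              any(s < placed$end + margin & e > placed$start - margin)) next
          placed <- rbind(placed, data.frame(start = s, end = e))
          ok <- TRUE
          break
        }
        if (!ok) stop("infeasible configuration: cannot place gap of length ",
                      glens[i], " on ", tn)
      }
      placed <- placed[order(placed$start), , drop = FALSE]
      gaps <- rbind(gaps, data.frame(target = tn, start = placed$start,
                                     end = placed$end,
                                     stringsAsFactors = FALSE))
      # carve the N-runs
      s <- seqs[[tn]]
      for (i in seq_len(nrow(placed)))
        substr(s, placed$start[i] + 1L, placed$end[i]) <-
          strrep("N", placed$end[i] - placed$start[i])
      seqs[[tn]] <- s
    }
    features <- rbind(features, feats_t)
  }
  if (is.null(gaps))
    gaps <- data.frame(target = character(0), start = integer(0),
                       end = integer(0), stringsAsFactors = FALSE)
  gaps <- gaps[order(gaps$target, gaps$start), , drop = FALSE]
  gaps$gap_id <- sprintf("gap%03d", seq_len(nrow(gaps)))
  rownames(gaps) <- NULL
  if (is.null(features))
    features <- data.frame(target = character(0), start = integer(0),
                           end = integer(0), type = character(0),
                           gene_id = character(0), strand = character(0),
                           stringsAsFactors = FALSE)
  rownames(features) <- NULL
  list(sequences = seqs, gaps = gaps, features = features)
}

#' Build the donor genome with planted novel segments
#'
#' Replaces a chosen subset of gap N-runs with random novel sequence of the
#' same length (gap fills), inserts novel segments at non-gap points at least
#' `insert_mean` bp away from any gap, and applies SNPs at `snp_rate` outside
#' novel segments. Unfilled gaps remain N in the donor.
#'
#' @param reference Named character vector of reference sequences.
#' @param gaps Gap table from [build_reference()].
#' @param config A [sim_config()].
#' @param seed Seed for the donor draws (default `config$seed + 1`).
#' @return list with `donor` (named character), `truth` (one row per novel
#'   segment: `novel_id`, `kind`, `ref_target`, `ref_start`, `ref_end`,
#'   `donor_start`, `donor_end`, `length`, `sequence`) and `snps`
#'   (`target`, `pos`, `ref_base`, `donor_base`).
#' @export
build_donor <- function(reference, gaps, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  donor <- reference
  truth <- NULL
  snps <- NULL

  # choose gaps to fill
  fill_idx <- if (config$n_novel_at_gap > 0)
    sort(sample(nrow(gaps), config$n_novel_at_gap)) else integer(0)

  # choose non-gap insertion points
  ins <- NULL
  if (config$n_novel_nongap > 0) {
    tnames <- names(reference)
    tlens <- nchar(reference)
    for (i in seq_len(config$n_novel_nongap)) {
      len <- sample(seq(config$novel_length_range[1],
                        config$novel_length_range[2]), 1)
      ok <- FALSE
      for (a in 1:500) {
        tn <- sample(tnames, 1, prob = tlens)
        L <- tlens[[tn]]
        p <- floor(runif(1, 2L * config$insert_mean,
                         L - 2L * config$insert_mean))
        g <- gaps[gaps$target == tn, , drop = FALSE]
        if (nrow(g) > 0 && any(p > g$start - config$insert_mean &
                               p < g$end + config$insert_mean)) next
        if (!is.null(ins) &&
            any(ins$target == tn &
                abs(ins$point - p) < 2L * config$insert_mean)) next
        ins <- rbind(ins, data.frame(target = tn, point = p, length = len,
                                     stringsAsFactors = FALSE))
        ok <- TRUE
        break
      }
      if (!ok) stop("infeasible configuration: cannot place non-gap insertion")
    }
    ins <- ins[order(ins$target, ins$point), , drop = FALSE]
  }

  # SNPs on reference coordinates, outside N runs and outside filled gaps
  for (tn in names(reference)) {
    s <- donor[[tn]]
    if (config$snp_rate > 0) {
      bases <- strsplit(s, "")[[1]]
      eligible <- which(bases %in% c("A", "C", "G", "T"))
      n_snp <- rbinom(1, length(eligible), config$snp_rate)
      if (n_snp > 0) {
        pos <- sort(sample(eligible, n_snp))
        old <- bases[pos]
        new <- vapply(old, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                      character(1))
        bases[pos] <- new
        s <- paste(bases, collapse = "")
        snps <- rbind(snps, data.frame(target = tn, pos = pos - 1L,
                                       ref_base = old, donor_base = new,
                                       stringsAsFactors = FALSE,
                                       row.names = NULL))
      }
    }
    donor[[tn]] <- s
  }

  # gap fills (same length as the gap: reference coordinates are preserved)
  if (length(fill_idx) > 0) {
    for (j in seq_along(fill_idx)) {
      g <- gaps[fill_idx[j], ]
      len <- g$end - g$start
      fill <- random_dna(len, gc = config$gc)
      s <- donor[[g$target]]
      substr(s, g$start + 1L, g$end) <- fill
      donor[[g$target]] <- s
      truth <- rbind(truth, data.frame(
        novel_id = sprintf("novel_gapfill_%02d", j), kind = "gap_fill",
        ref_target = g$target, ref_start = g$start, ref_end = g$end,
        donor_start = g$start, donor_end = g$end,   # shifted below
        length = len, sequence = fill, stringsAsFactors = FALSE))
    }
  }

  # non-gap insertions (shift donor coordinates)
  if (!is.null(ins)) {
    for (tn in unique(ins$target)) {
      it <- ins[ins$target == tn, , drop = FALSE]
      novel <- vapply(it$length, random_dna, character(1), gc = config$gc)
      s <- donor[[tn]]
      pieces <- character(0)
      prev <- 0L
      for (i in seq_len(nrow(it))) {
        pieces <- c(pieces, substr(s, prev + 1L, it$point[i]), novel[i])
        prev <- it$point[i]
      }
      pieces <- c(pieces, substr(s, prev + 1L, nchar(s)))
      donor[[tn]] <- paste(pieces, collapse = "")
      shift <- cumsum(c(0L, it$length))[seq_len(nrow(it))]
      truth <- rbind(truth, data.frame(
        novel_id = sprintf("novel_ins_%02d", seq_len(nrow(it)) +
                             sum(!is.null(truth) & FALSE)),
        kind = "nongap_insertion",
        ref_target = tn, ref_start = it$point, ref_end = it$point,
        donor_start = it$point + shift, donor_end = it$point + shift + it$length,
        length = it$length, sequence = novel, stringsAsFactors = FALSE))
    }
    # shift donor coordinates of gap fills that lie right of insertions
    gf <- which(truth$kind == "gap_fill")
    for (j in gf) {
      tn <- truth$ref_target[j]
      it <- ins[ins$target == tn, , drop = FALSE]
      sh <- sum(it$length[it$point <= truth$ref_start[j]])
      truth$donor_start[j] <- truth$ref_start[j] + sh
      truth$donor_end[j] <- truth$ref_end[j] + sh
    }
  }
  if (is.null(truth))
    truth <- data.frame(novel_id = character(0), kind = character(0),
                        ref_target = character(0), ref_start = integer(0),
                        ref_end = integer(0), donor_start = integer(0),
                        donor_end = integer(0), length = integer(0),
                        sequence = character(0), stringsAsFactors = FALSE)
  if (is.null(snps))
    snps <- data.frame(target = character(0), pos = integer(0),
                       ref_base = character(0), donor_base = character(0),
                       stringsAsFactors = FALSE)
  truth <- truth[order(truth$ref_target, truth$ref_start), , drop = FALSE]
  # renumber insertion ids deterministically after the sort
  nidx <- which(truth$kind == "nongap_insertion")
  truth$novel_id[nidx] <- sprintf("novel_ins_%02d", seq_along(nidx))
  rownames(truth) <- NULL
  list(donor = donor, truth = truth, snps = snps)
}

#' Simulate paired-end reads from the donor genome
#'
#' Fragments are drawn uniformly with insert length
#' `Normal(insert_mean, insert_sd)` truncated to at least `read_length`.
#' Mate 1 is the fragment's 5' read, mate 2 the reverse complement of its 3'
#' read. Substitution errors are applied at `base_error_rate`; qualities are
#' constant phred 37 with a low-quality (phred 2) tail on a configurable
#' fraction of reads. Fragments that would contain N (unfilled donor gaps)
#' are redrawn, as a sequencer reports no such reads. Read names encode the
#' true fragment coordinates (`sample:fragNNN:target:start:end`).
#'
#' @param donor Named character vector of donor sequences.
#' @param config A [sim_config()].
#' @param seed Seed for the read draws.
#' @param sample_id Sample label used in read names.
#' @return Paired-read data.frame (`id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @export
simulate_reads <- function(donor, config, seed = config$seed + 10L,
                           sample_id = "S1") {
  stopifnot(inherits(config, "sim_config"))
  if (config$coverage <= 0) stop("coverage must be positive")
  set.seed(seed)
  rl <- config$read_length
  out <- NULL
  for (tn in names(donor)) {
    s <- donor[[tn]]
    L <- nchar(s)
    if (L <= config$insert_mean + 4 * config$insert_sd)
      stop("donor target ", tn, " too short for the insert model")
    n <- round(config$coverage * L / (2 * rl))
    if (n == 0) next
    nruns <- find_gaps(setNames(s, tn))
    draw <- function(m) {
      ins <- pmin(L, pmax(rl, round(rnorm(m, config$insert_mean, config$insert_sd))))
      st <- floor(runif(m) * (L - ins + 1))
      data.frame(start = st, insert = ins)
    }
    fr <- draw(n)
    if (nrow(nruns) > 0) {
      for (it in 1:50) {
        bad <- rep(FALSE, nrow(fr))
        for (i in seq_len(nrow(nruns)))
          bad <- bad | (fr$start < nruns$end[i] & fr$start + fr$insert > nruns$start[i])
        if (!any(bad)) break
        fr[bad, ] <- draw(sum(bad))
        if (it == 50) stop("could not draw N-free fragments")
      }
    }
    m1 <- substring(s, fr$start + 1L, fr$start + rl)
    m2 <- cpp_revcomp(substring(s, fr$start + fr$insert - rl + 1L,
                                fr$start + fr$insert))
    add_errors <- function(reads) {
      nerr <- rbinom(length(reads), rl, config$base_error_rate)
      for (i in which(nerr > 0)) {
        pos <- sample.int(rl, nerr[i])
        for (p in pos) {
          old <- substr(reads[i], p, p)
          substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
        }
      }
      reads
    }
    if (config$base_error_rate > 0) {
      m1 <- add_errors(m1)
      m2 <- add_errors(m2)
    }
    tailq <- function(m) {
      tl <- ifelse(runif(m) < config$lowq_tail_frac, sample(5:15, m, TRUE), 0L)
      paste0(strrep("F", rl - tl), strrep("#", tl))
    }
    q1 <- tailq(n); q2 <- tailq(n)
    ids <- sprintf("%s:frag%07d:%s:%d:%d", sample_id, seq_len(n), tn,
                   fr$start, fr$start + fr$insert)
    out <- rbind(out, data.frame(id = ids, seq1 = m1, qual1 = q1,
                                 seq2 = unname(m2), qual2 = q2,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Parse the fragment coordinates encoded in simulated read names
#' @param ids Read names from [simulate_reads()].
#' @return data.frame with `sample`, `target`, `start`, `end`.
#' @export
parse_frag_coords <- function(ids) {
  f <- strsplit(ids, ":", fixed = TRUE)
  data.frame(sample = vapply(f, `[[`, character(1), 1),
             target = vapply(f, `[[`, character(1), 3),
             start = as.integer(vapply(f, `[[`, character(1), 4)),
             end = as.integer(vapply(f, `[[`, character(1), 5)),
             stringsAsFactors = FALSE)
}

simulate_bacs <- function(reference, gaps, seed) {
  set.seed(seed)
  bacs <- NULL
  for (tn in names(reference)) {
    L <- nchar(reference[[tn]])
    pos <- 0L
    while (pos < L) {
      len <- sample(20000:150000, 1)
      e <- min(L, pos + len)
      bacs <- rbind(bacs, data.frame(target = tn, start = pos, end = e,
                                     stringsAsFactors = FALSE))
      pos <- e + sample(0:2000, 1)
    }
  }
  # leave ~20% of gaps without BAC support so the cross-reference has signal
  if (nrow(gaps) > 0) {
    drop <- gaps[runif(nrow(gaps)) < 0.2, , drop = FALSE]
    if (nrow(drop) > 0) {
      keep <- rep(TRUE, nrow(bacs))
      for (i in seq_len(nrow(drop)))
        keep <- keep & !(bacs$target == drop$target[i] &
                         bacs$start < drop$end[i] & bacs$end > drop$start[i])
      bacs <- bacs[keep, , drop = FALSE]
    }
  }
  bacs$name <- sprintf("bac%04d", seq_len(nrow(bacs)))
  rownames(bacs) <- NULL
  bacs
}

#' Generate the full synthetic dataset
#'
#' Runs [build_reference()], [build_donor()] and [simulate_reads()] for each
#' sample, simulates BAC-insert placements, and optionally writes everything
#' to disk (`reference.fa`, `donor.fa`, `reads_<sample>_[12].fastq`,
#' `gaps.bed`, `genes.gff3`, `genes.bed`, `bacs.bed`, `truth.tsv`,
#' `config.json`).
#'
#' @param config A [sim_config()].
#' @param n_samples Number of donor samples to sequence (all share the donor
#'   genome; reads differ by seed).
#' @param dir Output directory, or `NULL` to keep everything in memory.
#' @param group Group (population) label for the sample manifest.
#' @return list with `config`, `reference` (sequences/gaps/features), `donor`,
#'   `truth`, `snps`, `bacs`, `reads` (named list of paired-read tables) and
#'   `manifest`.
#' @export
simulate_dataset <- function(config = sim_config(), n_samples = 3L,
                             dir = NULL, group = "group1") {
  ref <- build_reference(config)
  don <- build_donor(ref$sequences, ref$gaps, config)
  bacs <- simulate_bacs(ref$sequences, ref$gaps, seed = config$seed + 5L)
  samples <- sprintf("S%02d", seq_len(n_samples))
  reads <- lapply(seq_len(n_samples), function(s)
    simulate_reads(don$donor, config, seed = config$seed + 10L + s,
                   sample_id = samples[s]))
  names(reads) <- samples
  manifest <- data.frame(sample = samples, group = group,
                         stringsAsFactors = FALSE)
  ds <- list(config = config, reference = ref, donor = don$donor,
             truth = don$truth, snps = don$snps, bacs = bacs,
             reads = reads, manifest = manifest)
  class(ds) <- "sim_dataset"
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(ref$sequences, file.path(dir, "reference.fa"))
    write_fasta(don$donor, file.path(dir, "donor.fa"))
    g <- ref$gaps; g$name <- g$gap_id
    write_bed(g[, c("target", "start", "end", "name")], file.path(dir, "gaps.bed"))
    if (nrow(ref$features) > 0) {
      write_gff3(ref$features, file.path(dir, "genes.gff3"))
      write_bed12(ref$features, file.path(dir, "genes.bed"))
    }
    write_bed(bacs, file.path(dir, "bacs.bed"))
    write_truth(don$truth, file.path(dir, "truth.tsv"))
    for (s in samples)
      write_paired_fastq(reads[[s]],
                         file.path(dir, sprintf("reads_%s_1.fastq", s)),
                         file.path(dir, sprintf("reads_%s_2.fastq", s)))
    write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  ds
}
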