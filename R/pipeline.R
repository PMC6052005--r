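## End-to-end orchestration: triage -> primary assembly per sample ->
## secondary per group -> QC -> novelty screen -> OEA placement ->
## verification -> gap analysis. Stage outputs are plain files with
## documented schemas; the orchestrator holds no hidden state, so a run can
## resume from any stage directory.

PIPELINE_STAGES <- c("triage", "assemble", "qc", "screen", "place", "gaps")

#' Pipeline parameters
#'
#' @param trim A [trim_policy()].
#' @param min_identity Mapper identity threshold.
#' @param insert_tolerance Concordance tolerance multiplier.
#' @param include_discordant Route discordant both-mapped pairs to the
#'   assembly pool.
#' @param primary_min_overlap,secondary_min_overlap Assembly overlap
#'   thresholds (bp) for the read and contig tiers.
#' @param asm_min_identity Assembly overlap identity.
#' @param min_contig_length Minimum secondary-contig length (0 disables).
#' @param min_mapq Uniqueness threshold for OEA anchors (both sides).
#' @param min_support Minimum anchors per placement locus.
#' @param qc_drop_contaminant Drop contigs flagged by the contaminant screen.
#' @param contaminant_kmers Optional contaminant k-mer set.
#' @param verify_classes Placement classes to verify by realignment.
#' @return list of parameters.
#' @export
pipeline_params <- function(trim = trim_policy(), min_identity = 0.9,
                            insert_tolerance = 3, include_discordant = TRUE,
                            primary_min_overlap = 40L,
                            secondary_min_overlap = 100L,
                            asm_min_identity = 0.97,
                            min_contig_length = 0L,
                            min_mapq = 30L, min_support = 2L,
                            qc_drop_contaminant = FALSE,
                            contaminant_kmers = NULL,
                            verify_classes = "SINGLE") {
  as.list(environment())
}

#' Load a simulated dataset directory
#'
#' Reads the files written by [simulate_dataset()] back into the in-memory
#' dataset layout.
#'
#' @param dir Dataset directory.
#' @return A `sim_dataset`-shaped list.
#' @export
load_dataset <- function(dir) {
  cfgl <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- do.call(sim_config, cfgl[setdiff(names(cfgl), c())])
  sequences <- read_fasta(file.path(dir, "reference.fa"))
  gaps <- read_bed(file.path(dir, "gaps.bed"))
  names(gaps)[names(gaps) == "name"] <- "gap_id"
  features <- if (file.exists(file.path(dir, "genes.gff3")))
    read_gff3(file.path(dir, "genes.gff3"))
  else data.frame(target = character(0), start = integer(0), end = integer(0),
                  type = character(0), gene_id = character(0),
                  strand = character(0), stringsAsFactors = FALSE)
  manifest <- read.delim(file.path(dir, "manifest.tsv"), stringsAsFactors = FALSE)
  reads <- lapply(manifest$sample, function(s)
    read_paired_fastq(file.path(dir, sprintf("reads_%s_1.fastq", s)),
                      file.path(dir, sprintf("reads_%s_2.fastq", s))))
  names(reads) <- manifest$sample
  truth <- if (file.exists(file.path(dir, "truth.tsv")))
    read_truth(file.path(dir, "truth.tsv")) else NULL
  bacs <- if (file.exists(file.path(dir, "bacs.bed")))
    read_bed(file.path(dir, "bacs.bed")) else NULL
  ds <- list(config = config,
             reference = list(sequences = sequences, gaps = gaps,
                              features = features),
             donor = if (file.exists(file.path(dir, "donor.fa")))
               read_fasta(file.path(dir, "donor.fa")) else NULL,
             truth = truth, snps = NULL, bacs = bacs, reads = reads,
             manifest = manifest)
  class(ds) <- "sim_dataset"
  ds
}

cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(NA_integer_)
    n <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    op <- regmatches(cg, gregexpr("[A-Z=]", cg))[[1]]
    sum(n[op %in% c("M", "D", "=", "X", "N")])
  }, integer(1), USE.NAMES = FALSE)
}

write_oea_sam <- function(oea, targets, path) {
  mapped <- data.frame(
    qname = oea$pair_id,
    flag = 1L + ifelse(oea$g_strand == "-", 16L, 0L) + 8L +
      ifelse(oea$anchored_mate == 1L, 64L, 128L),
    rname = oea$g_target, pos = oea$g_pos, mapq = oea$g_mapq,
    cigar = sprintf("%dM", oea$g_end - oea$g_pos),
    seq = "*", qual = "*", stringsAsFactors = FALSE)
  unmapped <- data.frame(
    qname = oea$pair_id, flag = 1L + 4L +
      ifelse(oea$anchored_mate == 1L, 128L, 64L),
    rname = NA, pos = NA, mapq = 0L, cigar = NA,
    seq = oea$mate_seq, qual = oea$mate_qual, stringsAsFactors = FALSE)
  aln <- rbind(mapped, unmapped)
  aln <- aln[order(aln$qname, aln$flag), ]
  write_sam(aln, targets, path)
}

read_oea_sam <- function(path) {
  s <- read_sam(path)
  a <- s$aln
  mp <- a[bitwAnd(a$flag, 4L) == 0L, , drop = FALSE]
  um <- a[bitwAnd(a$flag, 4L) != 0L, , drop = FALSE]
  um <- um[match(mp$qname, um$qname), , drop = FALSE]
  data.frame(pair_id = mp$qname, g_target = mp$rname, g_pos = mp$pos,
             g_end = mp$pos + cigar_ref_span(mp$cigar),
             g_strand = ifelse(bitwAnd(mp$flag, 16L) != 0L, "-", "+"),
             g_mapq = mp$mapq, mate_seq = um$seq, mate_qual = um$qual,
             anchored_mate = ifelse(bitwAnd(mp$flag, 64L) != 0L, 1L, 2L),
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_contig_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  full <- names(x)
  id <- sub("\\s.*$", "", full)
  desc <- sub("^\\S+\\s*", "", full)
  get_kv <- function(key) {
    v <- sub(sprintf(".*%s=([^ ]+).*", key), "\\1", desc)
    v[!grepl(sprintf("%s=", key), desc)] <- NA
    v
  }
  df <- data.frame(contig_id = id, sequence = toupper(as.character(x)),
                   stringsAsFactors = FALSE, row.names = NULL)
  nr <- suppressWarnings(as.integer(get_kv("n_reads")))
  if (!all(is.na(nr))) df$n_reads <- nr
  np <- suppressWarnings(as.integer(get_kv("n_primary")))
  if (!all(is.na(np))) df$n_primary <- np
  sa <- get_kv("samples")
  if (!all(is.na(sa))) {
    df$sample_ids <- sa
    df$n_samples <- lengths(strsplit(sa, ",", fixed = TRUE))
  }
  df
}

stage_msg <- function(verbose, ...) if (verbose) message("[gapfillr] ", ...)

#' Run the full pipeline
#'
#' Executes triage, two-tier assembly, QC, novelty screening, OEA placement,
#' verification and gap analysis over a (simulated or loaded) dataset. With
#' `out_dir`, every stage writes its outputs as plain files and the run can
#' later resume from any stage via `from`.
#'
#' @param dataset A `sim_dataset` (from [simulate_dataset()]) or a dataset
#'   directory path (see [load_dataset()]).
#' @param params [pipeline_params()].
#' @param out_dir Optional output directory for stage files.
#' @param from Stage to resume from (`"triage"` runs everything); earlier
#'   stages are reloaded from `out_dir`.
#' @param verbose Log one line per stage.
#' @return An object of class `gapfillr_run`.
#' @export
run_pipeline <- function(dataset, params = pipeline_params(), out_dir = NULL,
                         from = "triage", verbose = TRUE) {
  if (is.character(dataset)) dataset <- load_dataset(dataset)
  from <- match.arg(from, PIPELINE_STAGES)
  if (from != "triage" && is.null(out_dir))
    stop("resuming with `from` requires `out_dir`")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- dataset$config
  ref <- dataset$reference$sequences
  insert_mean <- cfg$insert_mean
  cluster_radius <- 2L * insert_mean
  pad <- 2L * insert_mean
  samples <- dataset$manifest$sample
  run <- function(stage) match(stage, PIPELINE_STAGES) >= match(from, PIPELINE_STAGES)
  save_files <- !is.null(out_dir)

  ref_index <- NULL
  need_ref_index <- function() {
    if (is.null(ref_index)) ref_index <<- seq_index(ref)
    ref_index
  }

  ## ---- stage 1: triage ----------------------------------------------------
  pools <- list(); oeas <- list(); counts <- list()
  if (run("triage")) {
    idx <- need_ref_index()
    for (s in samples) {
      tr <- trim_pairs(dataset$reads[[s]], params$trim)
      rd <- tr$reads
      a1 <- map_reads(idx, setNames(rd$seq1, rd$id),
                      min_identity = params$min_identity)
      a2 <- map_reads(idx, setNames(rd$seq2, rd$id),
                      min_identity = params$min_identity)
      cls <- classify_pairs(a1, a2, insert_mean, params$insert_tolerance)
      ex <- extract_unaligned_pool(rd, a1, a2, cls,
                                   include_discordant = params$include_discordant,
                                   n_discarded = tr$n_discarded)
      pools[[s]] <- ex$pool; oeas[[s]] <- ex$oea; counts[[s]] <- ex$counts
      stage_msg(verbose, "triage ", s, ": ",
                paste(names(ex$counts), ex$counts, sep = "=", collapse = " "))
      if (save_files) {
        write_paired_fastq(ex$pool,
                           file.path(out_dir, sprintf("pool_%s_1.fastq", s)),
                           file.path(out_dir, sprintf("pool_%s_2.fastq", s)))
        write_oea_sam(ex$oea, setNames(nchar(ref), names(ref)),
                      file.path(out_dir, sprintf("oea_%s.sam", s)))
      }
    }
    if (save_files) {
      ct <- do.call(rbind, lapply(samples, function(s)
        cbind(data.frame(sample = s), as.data.frame(t(counts[[s]])))))
      write_tsv(ct, file.path(out_dir, "class_counts.tsv"))
    }
  } else {
    for (s in samples) {
      pools[[s]] <- read_paired_fastq(
        file.path(out_dir, sprintf("pool_%s_1.fastq", s)),
        file.path(out_dir, sprintf("pool_%s_2.fastq", s)))
      oeas[[s]] <- read_oea_sam(file.path(out_dir, sprintf("oea_%s.sam", s)))
    }
    ct <- read.delim(file.path(out_dir, "class_counts.tsv"),
                     stringsAsFactors = FALSE)
    counts <- lapply(seq_len(nrow(ct)), function(i)
      unlist(ct[i, -1, drop = TRUE]))
    names(counts) <- ct$sample
  }

  ## ---- stage 2: assembly --------------------------------------------------
  if (run("assemble")) {
    primary <- list()
    for (s in samples) {
      p <- pools[[s]]
      seqs <- if (nrow(p) > 0)
        c(setNames(p$seq1, paste0(p$id, "/1")),
          setNames(p$seq2, paste0(p$id, "/2"))) else character(0)
      quals <- c(p$qual1, p$qual2)
      primary[[s]] <- assemble_greedy(seqs, quals,
                                      min_overlap = params$primary_min_overlap,
                                      min_identity = params$asm_min_identity,
                                      id_prefix = paste0(s, "_c"))
      stage_msg(verbose, "primary assembly ", s, ": ", length(seqs),
                " reads -> ", nrow(primary[[s]]), " contigs")
    }
    sec <- secondary_assembly(primary,
                              min_overlap = params$secondary_min_overlap,
                              min_identity = params$asm_min_identity,
                              min_length = params$min_contig_length)
    stage_msg(verbose, "secondary assembly: ", nrow(sec$contigs),
              " contigs (", nrow(sec$debris), " debris)")
    if (save_files) {
      for (s in samples)
        write_fasta(setNames(primary[[s]]$sequence, primary[[s]]$contig_id),
                    file.path(out_dir, sprintf("primary_%s.fasta", s)),
                    desc = sprintf("n_reads=%d", primary[[s]]$n_reads))
      write_fasta(setNames(sec$contigs$sequence, sec$contigs$contig_id),
                  file.path(out_dir, "secondary.fasta"),
                  desc = sprintf("n_primary=%d samples=%s",
                                 sec$contigs$n_primary, sec$contigs$sample_ids))
      write_fasta(setNames(sec$debris$sequence, sec$debris$contig_id),
                  file.path(out_dir, "debris.fasta"),
                  desc = sprintf("n_primary=%d samples=%s",
                                 sec$debris$n_primary, sec$debris$sample_ids))
      st <- rbind(
        do.call(rbind, lapply(samples, function(s)
          cbind(data.frame(tier = "primary", group = s),
                as.data.frame(assembly_stats(primary[[s]]))))),
        cbind(data.frame(tier = "secondary", group = "all"),
              as.data.frame(assembly_stats(sec$contigs))))
      write_tsv(st, file.path(out_dir, "assembly_stats.tsv"))
    }
  } else {
    primary <- lapply(samples, function(s)
      read_contig_fasta(file.path(out_dir, sprintf("primary_%s.fasta", s))))
    names(primary) <- samples
    sec <- list(contigs = read_contig_fasta(file.path(out_dir, "secondary.fasta")),
                debris = read_contig_fasta(file.path(out_dir, "debris.fasta")))
  }

  ## ---- stage 3: QC --------------------------------------------------------
  if (run("qc")) {
    qc <- contig_qc(sec$contigs, params$contaminant_kmers)
    keep <- is.na(qc$duplicate_of)
    if (params$qc_drop_contaminant) keep <- keep & !qc$contaminant
    contigs_qc <- sec$contigs[keep, , drop = FALSE]
    stage_msg(verbose, "QC: ", nrow(sec$contigs), " -> ", nrow(contigs_qc),
              " contigs after duplicate/contaminant removal")
    if (save_files) {
      write_tsv(qc, file.path(out_dir, "qc.tsv"))
      write_fasta(setNames(contigs_qc$sequence, contigs_qc$contig_id),
                  file.path(out_dir, "contigs_qc.fasta"))
    }
  } else {
    qc <- read.delim(file.path(out_dir, "qc.tsv"), stringsAsFactors = FALSE)
    contigs_qc <- read_contig_fasta(file.path(out_dir, "contigs_qc.fasta"))
    contigs_qc <- merge(contigs_qc, sec$contigs[, c("contig_id", "n_primary",
                                                    "sample_ids", "n_samples")],
                        by = "contig_id", all.x = TRUE, sort = TRUE)
  }

  ## ---- stage 4: novelty screen -------------------------------------------
  if (run("screen")) {
    scr <- screen_reference(contigs_qc, ref, index = need_ref_index())
    novel <- scr$novel
    stage_msg(verbose, "novelty screen: ", sum(scr$verdicts$status == "KNOWN"),
              " known removed, ", nrow(novel), " novel retained")
    if (save_files) {
      write_tsv(scr$verdicts, file.path(out_dir, "verdicts.tsv"))
      write_fasta(setNames(novel$sequence, novel$contig_id),
                  file.path(out_dir, "novel.fasta"))
    }
  } else {
    scr <- list(verdicts = read.delim(file.path(out_dir, "verdicts.tsv"),
                                      stringsAsFactors = FALSE))
    novel <- read_contig_fasta(file.path(out_dir, "novel.fasta"))
  }

  ## ---- stage 5: OEA placement --------------------------------------------
  oea_all <- do.call(rbind, oeas)
  if (run("place")) {
    if (nrow(novel) > 0 && nrow(oea_all) > 0) {
      cidx <- seq_index(setNames(novel$sequence, novel$contig_id))
      caln <- map_reads(cidx, setNames(oea_all$mate_seq, oea_all$pair_id),
                        min_identity = params$min_identity)
      anchors <- harvest_anchors(oea_all, caln,
                                 setNames(nchar(novel$sequence), novel$contig_id),
                                 min_mapq = params$min_mapq,
                                 insert_mean = insert_mean)
      pred <- predict_locus(anchors, insert_mean)
      n_predicted <- length(unique(caln$target[caln$mapped %in% TRUE]))
      cl <- cluster_placements(pred, novel$contig_id,
                               cluster_radius = cluster_radius,
                               min_support = params$min_support,
                               target_lengths = setNames(nchar(ref), names(ref)))
      placements <- verify_placements(cl$placements, novel, ref, pad = pad,
                                      classes = params$verify_classes)
      classification <- cl$classification
    } else {
      anchors <- pred <- NULL
      n_predicted <- 0L
      placements <- cluster_placements(
        data.frame(c_id = character(0), g_target = character(0),
                   pred_start = integer(0), contig_len = integer(0),
                   orientation = character(0)), novel$contig_id)$placements
      classification <- data.frame(contig_id = novel$contig_id,
                                   n_loci = integer(nrow(novel)),
                                   classification = rep("UNPLACED", nrow(novel)),
                                   stringsAsFactors = FALSE)
    }
    tbl2 <- placement_summary(classification, n_total = nrow(novel),
                              n_predicted = n_predicted)
    stage_msg(verbose, "placement: ", tbl2$single, " single, ", tbl2$two,
              " two, ", tbl2$multi, " multi-locus contigs")
    if (save_files) {
      if (!is.null(pred)) write_tsv(pred, file.path(out_dir, "anchors.tsv"))
      write_tsv(placements, file.path(out_dir, "placements.tsv"))
      write_tsv(classification, file.path(out_dir, "classification.tsv"))
      write_tsv(tbl2, file.path(out_dir, "placement_summary.tsv"))
      if (nrow(placements) > 0) {
        bed <- data.frame(target = placements$target, start = placements$start,
                          end = placements$end, name = placements$contig_id,
                          score = placements$support,
                          strand = placements$strand)
        write_bed(bed, file.path(out_dir, "placements.bed"))
      }
    }
  } else {
    placements <- read.delim(file.path(out_dir, "placements.tsv"),
                             stringsAsFactors = FALSE)
    classification <- read.delim(file.path(out_dir, "classification.tsv"),
                                 stringsAsFactors = FALSE)
    tbl2 <- read.delim(file.path(out_dir, "placement_summary.tsv"),
                       stringsAsFactors = FALSE)
    pred <- NULL
  }

  ## ---- stage 6: gap analysis ---------------------------------------------
  gaps <- dataset$reference$gaps
  if (is.null(gaps) || nrow(gaps) == 0) gaps <- find_gaps(ref)
  ok <- placements$classification %in% params$verify_classes &
    placements$verified %in% TRUE
  placed_ok <- placements[ok, , drop = FALSE]
  report <- gap_closure_report(placed_ok, gaps,
                               features = dataset$reference$features,
                               bacs = dataset$bacs)
  stage_msg(verbose, "gap analysis: ", report$aggregate$n_gaps_closed,
            " gaps closed, ", report$aggregate$total_filled_bp, " bp filled")
  if (save_files) {
    write_tsv(report$per_gap, file.path(out_dir, "per_gap.tsv"))
    write_tsv(report$assignments, file.path(out_dir, "gap_assignments.tsv"))
  }

  res <- structure(list(
    schema_version = "1.0",
    counts = counts,
    primary_stats = lapply(primary, assembly_stats),
    secondary_stats = assembly_stats(sec$contigs),
    secondary = sec$contigs, debris = sec$debris,
    qc = qc, verdicts = scr$verdicts, novel = novel,
    placements = placements, classification = classification,
    placement_summary = tbl2,
    report = report,
    no_novel_sequence = nrow(novel) == 0,
    params = params), class = "gapfillr_run")
  if (save_files)
    jsonlite::write_json(run_summary(res), file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  res
}

#' Compact run summary (the numbers behind the printed tables)
#' @param x A `gapfillr_run`.
#' @return Nested list of counts suitable for JSON export.
#' @export
run_summary <- function(x) {
  stopifnot(inherits(x, "gapfillr_run"))
  list(schema_version = x$schema_version,
       triage = lapply(x$counts, as.list),
       assembly = list(primary = x$primary_stats,
                       secondary = x$secondary_stats,
                       n_debris = nrow(x$debris)),
       novelty = as.list(table(x$verdicts$status)),
       placement = as.list(x$placement_summary),
       gaps = x$report$aggregate,
       no_novel_sequence = x$no_novel_sequence)
}

#' @export
print.gapfillr_run <- function(x, ...) {
  cat("gapfillr pipeline run\n")
  cat("  samples:", length(x$counts), "\n")
  if (x$no_novel_sequence) {
    cat("  no novel sequence detected (empty unaligned pool or all contigs known)\n")
    return(invisible(x))
  }
  s <- x$secondary_stats
  cat(sprintf("  secondary assembly: %d contigs, %d bp, N50 %d, largest %d\n",
              s$n_contigs, s$total_bp, s$n50_bp, s$largest_bp))
  cat(sprintf("  novelty: %d known removed, %d novel\n",
              sum(x$verdicts$status == "KNOWN"), nrow(x$novel)))
  t2 <- x$placement_summary
  cat(sprintf("  placement: %d single / %d two / %d multi loci\n",
              t2$single, t2$two, t2$multi))
  a <- x$report$aggregate
  cat(sprintf("  gaps: %d contigs in gaps, %d closed, %d bp filled\n",
              a$n_gap_contigs, a$n_gaps_closed, a$total_filled_bp))
  invisible(x)
}

#' @export
summary.gapfillr_run <- function(object, ...) run_summary(object)
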