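mk_oea <- function(pair_id, g_pos, g_end, g_strand, g_mapq = 60L,
                   mate_seq = strrep("A", 100)) {
  data.frame(pair_id = pair_id, g_target = "chr1", g_pos = g_pos,
             g_end = g_end, g_strand = g_strand, g_mapq = g_mapq,
             mate_seq = mate_seq, mate_qual = strrep("F", nchar(mate_seq)),
             anchored_mate = 1L, stringsAsFactors = FALSE)
}

mk_caln <- function(mapped, c_id, pos, ref_end, strand, mapq) {
  data.frame(query_id = "p", mapped = mapped, target = c_id, pos = pos,
             ref_end = ref_end, strand = strand, mapq = mapq,
             stringsAsFactors = FALSE)
}

test_that("anchors require mapq >= 30 on both the genome and the contig side", {
  lens <- c(ctg1 = 3000L)
  oea <- mk_oea("p", 10000L, 10100L, "+")
  good <- harvest_anchors(oea, mk_caln(TRUE, "ctg1", 10L, 110L, "-", 60L), lens)
  expect_equal(nrow(good), 1)
  expect_equal(good$contig_end, "FIVE_PRIME")
  # ambiguous contig-side mapping (mapq 0) removes the anchor
  amb <- harvest_anchors(oea, mk_caln(TRUE, "ctg1", 10L, 110L, "-", 0L), lens)
  expect_equal(nrow(amb), 0)
  expect_equal(unname(attr(amb, "counts")["low_contig_mapq"]), 1L)
  # low genome-side mapq removes it too
  oea_lo <- mk_oea("p", 10000L, 10100L, "+", g_mapq = 0L)
  expect_equal(nrow(harvest_anchors(
    oea_lo, mk_caln(TRUE, "ctg1", 10L, 110L, "-", 60L), lens)), 0)
  # monotonicity: dropping the threshold to 0 can only add anchors
  all_anchors <- harvest_anchors(
    oea_lo, mk_caln(TRUE, "ctg1", 10L, 110L, "-", 0L), lens, min_mapq = 0L)
  expect_equal(nrow(all_anchors), 1)
  # 3' end assignment
  a3 <- harvest_anchors(oea, mk_caln(TRUE, "ctg1", 2900L, 3000L, "+", 60L), lens)
  expect_equal(a3$contig_end, "THREE_PRIME")
})

test_that("predict_locus reproduces the hand-worked fragment geometry", {
  # genome mate +, g = 10,000, insert 290, reads 100, contig 2,000,
  # contig-side read at contig start on '-': forward placement at 10,190
  a <- data.frame(g_pos = 10000L, g_end = 10100L, g_strand = "+",
                  c_pos = 0L, c_end = 100L, c_strand = "-",
                  contig_len = 2000L, stringsAsFactors = FALSE)
  p <- predict_locus(a, 290L)
  expect_equal(p$pred_start, 10190L)
  expect_equal(p$pred_end, 12190L)
  expect_equal(p$orientation, "+")
  # mirrored: genome mate on '-', m = 10,000 + 100 - 290 = 9,810; the
  # contig's other end anchors left of the mate
  a2 <- data.frame(g_pos = 10000L, g_end = 10100L, g_strand = "-",
                   c_pos = 1900L, c_end = 2000L, c_strand = "+",
                   contig_len = 2000L, stringsAsFactors = FALSE)
  p2 <- predict_locus(a2, 290L)
  expect_equal(p2$pred_start, 9810L - 1900L)
  expect_equal(p2$orientation, "+")
  # degenerate geometry: insert equal to read length abuts the mate
  a3 <- a; a3$c_strand <- "-"
  p3 <- predict_locus(a3, 100L)
  expect_equal(p3$pred_start, 10000L)
})

test_that("simulated OEA pairs invert exactly for all four strand configurations", {
  set.seed(501)
  ref <- setNames(random_seq(5000), "chr1")
  true_start <- 2000L; L <- 800L
  contig_fw <- unname(substr(ref, true_start + 1, true_start + L))
  gidx <- seq_index(ref)
  for (contig_rc in c(FALSE, TRUE)) {
    contig <- if (contig_rc) oracle_revcomp(contig_fw) else contig_fw
    cidx <- seq_index(c(ctg = contig), k = 21)
    for (genome_minus in c(FALSE, TRUE)) {
      if (!genome_minus) {
        # anchored mate left of the contig, fragment extends right
        g <- 1850L
        mate_genome <- substring(ref, g + 1, g + 100)          # '+' read
        frag_end <- g + 290L
        mate_contig <- oracle_revcomp(substring(ref, frag_end - 99, frag_end))
      } else {
        # anchored mate right of the contig on '-', fragment extends left
        g <- 2820L
        mate_genome <- oracle_revcomp(substring(ref, g + 1, g + 100))
        frag_start <- g + 100L - 290L
        mate_contig <- substring(ref, frag_start + 1, frag_start + 100)
      }
      galn <- map_reads(gidx, setNames(mate_genome, "p"))
      expect_true(galn$mapped && galn$pos == g &&
                    galn$strand == (if (genome_minus) "-" else "+"))
      caln <- map_reads(cidx, setNames(mate_contig, "p"))
      expect_true(caln$mapped)
      oea <- mk_oea("p", galn$pos, galn$ref_end, galn$strand,
                    mate_seq = mate_contig)
      anc <- harvest_anchors(oea, caln, c(ctg = L))
      expect_equal(nrow(anc), 1)
      pred <- predict_locus(anc, 290L)
      expect_equal(pred$pred_start, true_start)
      expect_equal(pred$pred_end, true_start + L)
      expect_equal(pred$orientation, if (contig_rc) "-" else "+")
    }
  }
})

test_that("clustering pairs left and right evidence into loci and classifies multiplicity", {
  # collinear contig: left-end anchors at ~10,190, right-end agreeing
  pred <- data.frame(
    c_id = "c1", g_target = "chr1",
    pred_start = c(10190L, 10194L, 10201L, 10188L),
    contig_len = 2000L, orientation = "+",
    contig_end = c("FIVE_PRIME", "FIVE_PRIME", "FIVE_PRIME", "THREE_PRIME"),
    stringsAsFactors = FALSE)
  cl <- cluster_placements(pred, "c1", cluster_radius = 580L, min_support = 2L)
  expect_equal(nrow(cl$placements), 1)
  expect_equal(cl$placements$start, 10194L)   # median of 10190,10194,10201
  expect_equal(cl$placements$end, 10188L + 2000L)
  expect_equal(cl$placements$support, 4L)
  expect_equal(cl$classification$classification, "SINGLE")
  # two well-separated sites -> TWO; three -> MULTI
  two <- rbind(pred,
               transform(pred, pred_start = pred_start + 1000000L))
  cl2 <- cluster_placements(two, "c1")
  expect_equal(cl2$classification$classification, "TWO")
  three <- rbind(two, transform(pred, pred_start = pred_start + 2000000L))
  cl3 <- cluster_placements(three, "c1")
  expect_equal(cl3$classification$classification, "MULTI")
  # support below min_support -> UNPLACED
  weak <- pred[1, ]
  cl4 <- cluster_placements(weak, c("c1", "c9"))
  expect_true(all(cl4$classification$classification == "UNPLACED"))
})

test_that("an inserted contig's two junction ends reconcile into one short locus", {
  # insertion at reference point 50,000, contig 2,000 bp: left-end anchors
  # predict ~point, right-end anchors predict ~point - contig_len
  pred <- data.frame(
    c_id = "ins", g_target = "chr1",
    pred_start = c(49950L, 49960L, 48010L, 48020L),
    contig_len = 2000L, orientation = "+",
    contig_end = c("FIVE_PRIME", "FIVE_PRIME", "THREE_PRIME", "THREE_PRIME"),
    stringsAsFactors = FALSE)
  cl <- cluster_placements(pred, "ins")
  expect_equal(cl$classification$classification, "SINGLE")
  expect_equal(nrow(cl$placements), 1)
  expect_equal(cl$placements$start, 49955L)
  expect_equal(cl$placements$end, 48015L + 2000L)
  expect_equal(cl$placements$support, 4L)
})

test_that("verification accepts true placements and rejects forced wrong ones", {
  ds <- small_dataset()
  run <- small_run()
  plc <- run$placements[run$placements$classification == "SINGLE", ]
  expect_true(any(plc$verified))
  wrong <- plc[which(plc$verified)[1], , drop = FALSE]
  span <- wrong$end - wrong$start
  wrong$start <- 10L; wrong$end <- 10L + span
  w <- verify_placements(wrong, run$novel, ds$reference$sequences)
  expect_false(w$verified)
  # UNPLACED rows are untouched
  un <- wrong; un$classification <- "UNPLACED"; un$verified <- NA
  expect_true(is.na(verify_placements(un, run$novel,
                                      ds$reference$sequences)$verified))
})
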