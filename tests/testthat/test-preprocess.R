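phred_str <- function(q) intToUtf8(q + 33L, multiple = FALSE)

test_that("trimming applies end-clips, the sliding window, and the length floor", {
  pol <- trim_policy()
  # clean read: untouched
  r <- trim_reads(strrep("A", 60), strrep(phred_str(30), 60), pol)
  expect_true(r$keep)
  expect_equal(nchar(r$seq), 60)
  # 55 bp, last 6 bases phred 2: end-clip to 49 < 50, discarded
  q <- paste0(strrep(phred_str(30), 49), strrep(phred_str(2), 6))
  r <- trim_reads(strrep("A", 55), q, pol)
  expect_false(r$keep)
  # 100 bp, 70 good then 30 at phred 10: cut at the first failing window,
  # retaining the leading good bases of that window -> 70 bp
  q <- paste0(strrep(phred_str(30), 70), strrep(phred_str(10), 30))
  r <- trim_reads(strrep("A", 100), q, pol)
  expect_true(r$keep)
  expect_equal(nchar(r$seq), 70)
  # sequence/quality length mismatch errors
  expect_error(trim_reads("ACGT", "III"), "mismatch")
})

test_that("trimming is idempotent over random quality profiles", {
  set.seed(42)
  pol <- trim_policy()
  n_checked <- 0
  for (i in 1:50) {
    L <- sample(60:150, 1)
    q <- phred_str(sample(c(2:5, 15:40), L, TRUE,
                          prob = c(rep(0.01, 4), rep(0.96 / 26, 26))))
    s <- random_seq(L)
    t1 <- trim_reads(s, q, pol)
    if (!t1$keep) next
    n_checked <- n_checked + 1
    t2 <- trim_reads(t1$seq, t1$qual, pol)
    expect_true(t2$keep)
    expect_identical(t2$seq, t1$seq)
  }
  expect_gt(n_checked, 5)
})

test_that("pair classification follows fragment geometry", {
  mk <- function(mapped, target, pos, ref_end, strand, mapq = 60) {
    data.frame(mapped = mapped, target = target, pos = pos, ref_end = ref_end,
               strand = strand, mapq = mapq, stringsAsFactors = FALSE)
  }
  # forward mate at 10,000, reverse mate ending at 10,290: insert 290
  cls <- classify_pairs(mk(TRUE, "chr1", 10000L, 10100L, "+"),
                        mk(TRUE, "chr1", 10190L, 10290L, "-"), 290)
  expect_equal(as.character(cls$class), "MAPPED_CONCORDANT")
  # one mate unmapped -> OEA
  cls <- classify_pairs(mk(TRUE, "chr1", 10000L, 10100L, "+"),
                        mk(FALSE, NA, NA, NA, NA), 290)
  expect_equal(as.character(cls$class), "OEA")
  # neither mapped
  cls <- classify_pairs(mk(FALSE, NA, NA, NA, NA), mk(FALSE, NA, NA, NA, NA), 290)
  expect_equal(as.character(cls$class), "BOTH_UNMAPPED")
  expect_false(cls$discordant)
  # both mapped, absurd insert -> unaligned pool, flagged discordant
  cls <- classify_pairs(mk(TRUE, "chr1", 10000L, 10100L, "+"),
                        mk(TRUE, "chr1", 500000L, 500100L, "-"), 290)
  expect_equal(as.character(cls$class), "BOTH_UNMAPPED")
  expect_true(cls$discordant)
  # same strand -> discordant
  cls <- classify_pairs(mk(TRUE, "chr1", 10000L, 10100L, "+"),
                        mk(TRUE, "chr1", 10190L, 10290L, "+"), 290)
  expect_true(cls$discordant)
})

test_that("class counts are conserved and the pool matches the fragment-coordinate oracle", {
  ds <- small_dataset()
  cfg <- ds$config
  idx <- seq_index(ds$reference$sequences)
  tr <- trim_pairs(ds$reads$S01)
  rd <- tr$reads
  a1 <- map_reads(idx, setNames(rd$seq1, rd$id))
  a2 <- map_reads(idx, setNames(rd$seq2, rd$id))
  cls <- classify_pairs(a1, a2, cfg$insert_mean)
  ex <- extract_unaligned_pool(rd, a1, a2, cls, n_discarded = tr$n_discarded)
  expect_equal(sum(ex$counts), nrow(ds$reads$S01))

  # oracle: fragments wholly inside a novel donor segment must be in the
  # pool; fragments wholly outside any novel segment and away from
  # junctions must not be
  co <- parse_frag_coords(rd$id)
  tru <- ds$truth
  inside <- rep(FALSE, nrow(co))
  near <- rep(FALSE, nrow(co))
  for (i in seq_len(nrow(tru))) {
    inside <- inside | (co$start >= tru$donor_start[i] &
                          co$end <= tru$donor_end[i])
    near <- near | (co$end > tru$donor_start[i] - 200 &
                      co$start < tru$donor_end[i] + 200)
  }
  pool_ids <- ex$pool$id
  expect_true(all(rd$id[inside] %in% pool_ids))
  expect_equal(sum(pool_ids %in% rd$id[!near]), 0)
  # OEA pairs straddle junctions
  expect_true(all(ex$oea$pair_id %in% rd$id[near & !inside]))
})

test_that("an all-concordant set yields an empty pool and sidecar", {
  aln <- data.frame(mapped = TRUE, target = "chr1", pos = c(0L, 1000L),
                    ref_end = c(100L, 1100L), strand = "+", mapq = 60L,
                    stringsAsFactors = FALSE)
  aln2 <- aln; aln2$pos <- aln$pos + 190L; aln2$ref_end <- aln$ref_end + 190L
  aln2$strand <- "-"
  reads <- data.frame(id = c("p1", "p2"), seq1 = "A", qual1 = "F",
                      seq2 = "A", qual2 = "F", stringsAsFactors = FALSE)
  cls <- classify_pairs(aln, aln2, 290)
  ex <- extract_unaligned_pool(reads, aln, aln2, cls)
  expect_equal(nrow(ex$pool), 0)
  expect_equal(nrow(ex$oea), 0)
  expect_equal(unname(ex$counts["MAPPED_CONCORDANT"]), 2L)
})
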