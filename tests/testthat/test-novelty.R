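test_that("exact-containment contigs are KNOWN and removed; mutated or novel ones retained", {
  set.seed(401)
  ref <- setNames(random_seq(50000), "chr1")
  idx <- seq_index(ref)
  starts <- sample(1:(50000 - 400), 10)
  decoys <- substring(ref, starts, starts + 399)
  decoys[1:3] <- vapply(decoys[1:3], oracle_revcomp, character(1))
  mut <- decoys[4]
  substr(mut, 200, 200) <- if (substr(mut, 200, 200) == "A") "G" else "A"
  contigs <- data.frame(
    contig_id = c(sprintf("d%02d", 1:10), "mut", "nov"),
    sequence = c(decoys, mut, random_seq(400)),
    stringsAsFactors = FALSE)
  scr <- screen_reference(contigs, ref, idx)
  v <- scr$verdicts
  expect_true(all(v$status[1:10] == "KNOWN"))
  expect_true(all(v$best_identity[1:10] == 1 & v$best_coverage[1:10] == 1))
  # full-length single mismatch: PARTIAL, retained
  expect_equal(v$status[v$contig_id == "mut"], "PARTIAL")
  expect_lt(v$best_identity[v$contig_id == "mut"], 1)
  expect_equal(v$best_coverage[v$contig_id == "mut"], 1, tolerance = 0.02)
  # random contig: NOVEL
  expect_equal(v$status[v$contig_id == "nov"], "NOVEL")
  expect_setequal(scr$novel$contig_id, c("mut", "nov"))
})

test_that("truth-derived novel contigs are never screened out", {
  ds <- small_dataset()
  ref <- ds$reference$sequences
  contigs <- data.frame(contig_id = ds$truth$novel_id,
                        sequence = ds$truth$sequence,
                        stringsAsFactors = FALSE)
  scr <- screen_reference(contigs, ref)
  expect_true(all(scr$verdicts$status == "NOVEL"))
})

test_that("adding reference sequence never moves a verdict toward NOVEL", {
  set.seed(403)
  base <- setNames(random_seq(20000), "chr1")
  extra <- random_seq(5000)
  contigs <- data.frame(
    contig_id = c("inref", "inextra", "nowhere"),
    sequence = c(substr(base, 3001, 3400), substr(extra, 1001, 1400),
                 random_seq(400)),
    stringsAsFactors = FALSE)
  rank <- c(NOVEL = 0, PARTIAL = 1, KNOWN = 2)
  v1 <- screen_reference(contigs, base)$verdicts
  v2 <- screen_reference(contigs, c(base, chr2 = extra))$verdicts
  expect_true(all(rank[v2$status] >= rank[v1$status]))
  expect_equal(v2$status[2], "KNOWN")
})

test_that("outgroup read coverage separates reference-derived from novel contigs", {
  ds <- small_dataset()
  cfg <- ds$config
  ref <- ds$reference$sequences
  # contigs: all planted novel insertions (absent from the reference)
  contigs <- data.frame(
    contig_id = ds$truth$novel_id[ds$truth$kind == "nongap_insertion"],
    sequence = ds$truth$sequence[ds$truth$kind == "nongap_insertion"],
    stringsAsFactors = FALSE)
  # outgroup 1: reads simulated from the reference only -> no support
  refreads <- simulate_reads(ref, cfg, seed = 99, sample_id = "OG")
  cs_ref <- cross_sample_support(contigs, refreads)
  expect_equal(cs_ref$summary, 0)
  # outgroup 2: reads simulated from the donor -> contigs well covered
  donreads <- simulate_reads(ds$donor, cfg, seed = 100, sample_id = "OG2")
  cs_don <- cross_sample_support(contigs, donreads)
  expect_equal(cs_don$summary, 1)
  expect_true(all(cs_don$coverage$covered_fraction >= 0.9))
  # empty outgroup
  cs0 <- cross_sample_support(contigs, character(0))
  expect_true(all(cs0$coverage$covered_fraction == 0))
})
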