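test_that("find_gaps returns maximal N-runs including boundary cases", {
  g <- find_gaps(c(s = "ACGTNNNNACGT"))
  expect_equal(nrow(g), 1)
  expect_equal(c(g$start, g$end), c(4L, 8L))
  expect_equal(nrow(find_gaps(c(s = "ACGTACGT"))), 0)
  g2 <- find_gaps(c(s = "NNACGT"))
  expect_equal(c(g2$start, g2$end), c(0L, 2L))
  g3 <- find_gaps(c(s = "ACGTNn"))  # case-insensitive, run to the end
  expect_equal(c(g3$start, g3$end), c(4L, 6L))
})

test_that("find_gaps agrees with the run-length oracle on random sequences", {
  set.seed(601)
  for (i in 1:200) {
    ch <- sample(c("A", "C", "G", "T", "N"), sample(5:80, 1), TRUE,
                 prob = c(0.2, 0.2, 0.2, 0.2, 0.2))
    s <- paste(ch, collapse = "")
    got <- find_gaps(c(x = s))
    want <- oracle_nruns(s)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

# the hand-built toy: 3 gaps, 4 placed contigs, one gap closed by the union
# of two overlapping contigs
toy_gaps <- data.frame(target = "chr1",
                       start = c(1000L, 3000L, 5000L),
                       end = c(1500L, 3300L, 5200L),
                       gap_id = c("g1", "g2", "g3"),
                       stringsAsFactors = FALSE)
toy_placements <- data.frame(contig_id = c("c1", "c2", "c3", "c4"),
                             target = "chr1",
                             start = c(900L, 2900L, 3240L, 5100L),
                             end = c(1600L, 3250L, 3400L, 5150L),
                             stringsAsFactors = FALSE)
toy_features <- data.frame(
  target = "chr1",
  start = c(800L, 950L, 2900L, 3050L),
  end = c(950L, 2000L, 3050L, 4000L),
  type = c("exon", "intron", "exon", "intron"),
  gene_id = c("gA", "gA", "gB", "gB"),
  strand = "+", stringsAsFactors = FALSE)
toy_bacs <- data.frame(target = "chr1", start = 0L, end = 4000L,
                       stringsAsFactors = FALSE)

test_that("gap intersection computes per-gap fill and union closure", {
  ig <- intersect_gaps(toy_placements, toy_gaps)
  pg <- ig$per_gap
  # g1: contained in c1 -> filled 500, closed
  expect_equal(pg$filled_bp[1], 500)
  expect_true(pg$closed[1])
  # g2: c2 fills [3000,3250), c3 fills [3240,3300): union covers -> closed
  expect_equal(pg$filled_bp[2], 300)
  expect_true(pg$closed[2])
  # g3: c4 fills 50 of 200, open
  expect_equal(pg$filled_bp[3], 50)
  expect_false(pg$closed[3])
  # assignments carry per-pair overlaps
  expect_equal(ig$assignments$overlap_bp[
    ig$assignments$contig_id == "c2"], 250)
  # conservation: filled never exceeds gap length
  expect_true(all(pg$filled_bp <= pg$end - pg$start))
  expect_error(intersect_gaps(transform(toy_placements, end = start - 1),
                              toy_gaps), "malformed")
})

test_that("interval overlaps agree with a per-base membership oracle", {
  set.seed(603)
  for (i in 1:100) {
    s1 <- sample(0:9000, 1); e1 <- s1 + sample(1:1000, 1)
    s2 <- sample(0:9000, 1); e2 <- s2 + sample(1:1000, 1)
    plc <- data.frame(contig_id = "c", target = "t", start = s1, end = e1)
    gap <- data.frame(target = "t", start = s2, end = e2, gap_id = "g")
    ig <- intersect_gaps(plc, gap)
    expect_equal(ig$per_gap$filled_bp, oracle_overlap_bp(s1, e1, s2, e2))
  }
})

test_that("genic classification labels every overlapped feature class", {
  g <- classify_genic(toy_gaps, toy_features)
  # g1 sits inside gA's intron only
  expect_true(g$genic[1]); expect_equal(g$classes[1], "intron")
  # g2 spans gB's exon-intron boundary: exon, 2 bp splice window, intron
  expect_true(g$exon[2] && g$splice_site[2] && g$intron[2])
  expect_equal(g$classes[2], "exon,splice_site,intron")
  # g3 intergenic
  expect_false(g$genic[3])
  expect_warning(classify_genic(toy_gaps,
                                transform(toy_features, type = "mystery")),
                 "unknown feature type")
})

test_that("BAC cross-reference separates covered from novel-no-BAC gap contigs", {
  ig <- intersect_gaps(toy_placements, toy_gaps)
  bx <- bac_crossref(toy_placements, ig$assignments, toy_bacs)
  expect_true(all(bx$bac_covered[c("c1", "c2", "c3")]))
  expect_false(bx$bac_covered[["c4"]])
  expect_equal(bx$novel_no_bac_contigs, "c4")
  expect_equal(bx$novel_no_bac_gaps, "g3")
  expect_warning(bac_crossref(toy_placements, ig$assignments, NULL),
                 "no BAC placements")
})

test_that("the closure report aggregates match hand-computed values", {
  rep <- suppressWarnings(
    gap_closure_report(toy_placements, toy_gaps, toy_features, toy_bacs))
  a <- rep$aggregate
  expect_equal(a$n_gap_contigs, 4)
  expect_equal(a$n_gaps_hit, 3)
  expect_equal(a$n_gaps_closed, 2)
  expect_equal(a$total_filled_bp, 850)
  expect_equal(a$n_genic_gaps_hit, 2)
  expect_equal(a$n_genic_gap_contigs, 3)
  expect_equal(a$n_novel_no_bac, 1)
  expect_output(print(rep), "gaps hit / closed:")
})
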