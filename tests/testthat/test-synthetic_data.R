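test_that("reference gaps equal independently rescanned maximal N-runs", {
  cfg <- sim_config(seed = 11, genome_length = 1e5, n_gaps = 3,
                    gap_length_range = c(200, 500), n_novel_at_gap = 2,
                    n_novel_nongap = 1, n_genes = 4)
  ref <- build_reference(cfg)
  runs <- oracle_nruns(ref$sequences[["chr1"]])
  expect_equal(nrow(runs), 3)
  expect_equal(runs$start, ref$gaps$start)
  expect_equal(runs$end, ref$gaps$end)
  lens <- ref$gaps$end - ref$gaps$start
  expect_true(all(lens >= 200 & lens <= 500))
})

test_that("a gapless configuration yields an N-free reference and empty gap table", {
  cfg <- sim_config(seed = 5, genome_length = 5e4, n_gaps = 0,
                    n_novel_at_gap = 0, n_genes = 2)
  ref <- build_reference(cfg)
  expect_equal(nrow(ref$gaps), 0)
  expect_false(grepl("N", ref$sequences[["chr1"]], fixed = TRUE))
})

test_that("gene models are non-overlapping with >= 2 exons, UTRs and introns", {
  cfg <- sim_config(seed = 7, genome_length = 2e5, n_gaps = 4,
                    n_novel_at_gap = 2, n_novel_nongap = 2, n_genes = 10)
  ref <- build_reference(cfg)
  f <- ref$features
  coding <- unique(f$gene_id[f$type == "exon"])
  for (g in coding) {
    fg <- f[f$gene_id == g, ]
    expect_gte(sum(fg$type == "exon"), 2)
    expect_gte(sum(fg$type == "intron"), 1)
    expect_true(all(c("five_prime_UTR", "three_prime_UTR") %in% fg$type))
  }
  spans <- do.call(rbind, lapply(unique(f$gene_id), function(g)
    data.frame(start = min(f$start[f$gene_id == g]),
               end = max(f$end[f$gene_id == g]))))
  spans <- spans[order(spans$start), ]
  expect_true(all(diff(spans$start) > 0))
  expect_true(all(spans$end[-nrow(spans)] <= spans$start[-1]))
  # some gaps genic, some not
  genic <- classify_genic(ref$gaps, f)
  expect_true(any(genic$genic) && any(!genic$genic))
})

test_that("generator is byte-deterministic under a fixed seed", {
  cfg <- sim_config(seed = 9, genome_length = 5e4, n_gaps = 2,
                    gap_length_range = c(100, 200), n_novel_at_gap = 1,
                    n_novel_nongap = 1, novel_length_range = c(500, 800),
                    coverage = 4, n_genes = 3)
  d1 <- simulate_dataset(cfg, n_samples = 1)
  d2 <- simulate_dataset(cfg, n_samples = 1)
  expect_identical(d1$reference, d2$reference)
  expect_identical(d1$donor, d2$donor)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$reads, d2$reads)
})

test_that("donor reconstructed from reference + truth + SNPs matches exactly", {
  cfg <- sim_config(seed = 13, genome_length = 1e5, n_gaps = 3,
                    gap_length_range = c(200, 400), n_novel_at_gap = 2,
                    n_novel_nongap = 2, novel_length_range = c(400, 900),
                    n_genes = 3, snp_rate = 1e-3)
  ref <- build_reference(cfg)
  don <- build_donor(ref$sequences, ref$gaps, cfg)
  rebuilt <- oracle_reconstruct_donor(ref$sequences, don$truth, don$snps)
  expect_identical(rebuilt, don$donor)
  # truth coordinates point at the right donor substrings
  for (i in seq_len(nrow(don$truth))) {
    tr <- don$truth[i, ]
    expect_identical(substr(don$donor[[tr$ref_target]],
                            tr$donor_start + 1, tr$donor_end), tr$sequence)
  }
})

test_that("a donor with nothing planted equals the reference", {
  cfg <- sim_config(seed = 17, genome_length = 5e4, n_gaps = 2,
                    gap_length_range = c(100, 200), n_novel_at_gap = 0,
                    n_novel_nongap = 0, snp_rate = 0, n_genes = 2)
  ref <- build_reference(cfg)
  don <- build_donor(ref$sequences, ref$gaps, cfg)
  expect_identical(don$donor, ref$sequences)
  expect_equal(nrow(don$truth), 0)
})

test_that("gap-fill truth records coincide with emitted gap intervals", {
  ds <- small_dataset()
  fills <- ds$truth[ds$truth$kind == "gap_fill", ]
  key <- paste(ds$reference$gaps$target, ds$reference$gaps$start,
               ds$reference$gaps$end)
  expect_true(all(paste(fills$ref_target, fills$ref_start, fills$ref_end)
                  %in% key))
  # non-gap insertions are points
  ins <- ds$truth[ds$truth$kind == "nongap_insertion", ]
  expect_true(all(ins$ref_start == ins$ref_end))
  expect_true(all(grepl("^[ACGT]+$", ds$truth$sequence)))
})

test_that("error-free reads are exact donor substrings and pair count follows coverage", {
  cfg <- sim_config(seed = 19, genome_length = 1e5, n_gaps = 0,
                    n_novel_at_gap = 0, n_novel_nongap = 0, snp_rate = 0,
                    base_error_rate = 0, lowq_tail_frac = 0, coverage = 10,
                    n_genes = 0)
  ref <- build_reference(cfg)
  reads <- simulate_reads(ref$sequences, cfg, seed = 21)
  expect_equal(nrow(reads), round(10 * 1e5 / (2 * 100)))
  donor <- ref$sequences[["chr1"]]
  co <- parse_frag_coords(reads$id)
  m1 <- substring(donor, co$start + 1, co$start + 100)
  m2 <- substring(donor, co$end - 99, co$end)
  expect_identical(reads$seq1, m1)
  expect_identical(unname(as.character(reads$seq2)),
                   unname(vapply(m2, oracle_revcomp, character(1))))
})

test_that("infeasible gap placement raises an explicit error", {
  cfg <- sim_config(seed = 1, genome_length = 6000, n_gaps = 8,
                    gap_length_range = c(500, 600), n_novel_at_gap = 0,
                    n_genes = 0)
  expect_error(build_reference(cfg), "infeasible")
})
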