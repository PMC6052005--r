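test_that("error-free tiling reads assemble into the exact planted segment", {
  set.seed(201)
  seg <- random_seq(500)
  starts <- unique(sort(c(1, sample(1:400, 40, replace = TRUE), 401)))
  reads <- substring(seg, starts, starts + 99)
  names(reads) <- sprintf("r%03d", seq_along(reads))
  flip <- seq_along(reads) %% 3 == 0
  reads[flip] <- vapply(reads[flip], oracle_revcomp, character(1))
  asm <- assemble_greedy(reads)
  expect_equal(nrow(asm), 1)
  expect_true(asm$sequence == seg || asm$sequence == oracle_revcomp(seg))
  expect_equal(asm$n_reads, length(reads))
})

test_that("non-overlapping and duplicate reads behave as expected", {
  seg <- random_seq(600)
  two <- assemble_greedy(c(a = substr(seg, 1, 100), b = substr(seg, 301, 400)))
  expect_equal(nrow(two), 2)
  dup <- assemble_greedy(c(a = substr(seg, 1, 100), b = substr(seg, 1, 100)))
  expect_equal(nrow(dup), 1)
  expect_equal(dup$n_reads, 2)
  empty <- assemble_greedy(character(0))
  expect_equal(nrow(empty), 0)
})

test_that("every input read is assigned to exactly one contig", {
  set.seed(203)
  seg1 <- random_seq(400); seg2 <- random_seq(400)
  starts <- sample(1:300, 30, replace = TRUE)
  reads <- c(substring(seg1, starts, starts + 99),
             substring(seg2, starts, starts + 99),
             vapply(1:5, function(i) random_seq(100), character(1)))
  names(reads) <- sprintf("r%03d", seq_along(reads))
  asm <- assemble_greedy(reads)
  mem <- attr(asm, "members")
  expect_setequal(mem$read_id, names(reads))
  expect_equal(anyDuplicated(mem$read_id), 0)
  expect_equal(sum(asm$n_reads), length(reads))
})

test_that("consensus from noisy reads still matches the true segment", {
  set.seed(205)
  seg <- random_seq(500)
  starts <- unique(sort(c(1, sample(1:400, 60, replace = TRUE), 401)))
  reads <- substring(seg, starts, starts + 99)
  # 0.5% substitution errors
  reads <- vapply(reads, function(r) {
    ch <- strsplit(r, "")[[1]]
    n <- rbinom(1, length(ch), 0.005)
    if (n > 0) {
      at <- sample(length(ch), n)
      ch[at] <- vapply(ch[at], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    }
    paste(ch, collapse = "")
  }, character(1))
  names(reads) <- sprintf("r%03d", seq_along(reads))
  asm <- assemble_greedy(reads)
  expect_equal(nrow(asm), 1)
  expect_true(asm$sequence == seg || asm$sequence == oracle_revcomp(seg))
})

test_that("secondary assembly merges shared segments and excludes singlets as debris", {
  set.seed(207)
  shared <- random_seq(1000)
  private <- random_seq(600)
  mk_primary <- function(seqs) {
    data.frame(contig_id = sprintf("c%02d", seq_along(seqs)), sequence = seqs,
               n_reads = rep(10L, length(seqs)), stringsAsFactors = FALSE)
  }
  primary <- list(
    S1 = mk_primary(substr(shared, 1, 700)),
    S2 = mk_primary(substr(shared, 301, 1000)),
    S3 = mk_primary(c(substr(shared, 101, 900), private)))
  sec <- secondary_assembly(primary)
  expect_equal(nrow(sec$contigs), 1)
  expect_equal(sec$contigs$n_samples, 3)
  expect_equal(sec$contigs$sample_ids, "S1,S2,S3")
  expect_true(sec$contigs$sequence == shared ||
                sec$contigs$sequence == oracle_revcomp(shared))
  # the private contig is a singlet -> debris
  expect_equal(nrow(sec$debris), 1)
  expect_true(sec$debris$sequence %in% c(private, oracle_revcomp(private)))
  # empty input
  e <- secondary_assembly(list(S1 = mk_primary(character(0))))
  expect_equal(nrow(e$contigs), 0)
})

test_that("assembly statistics match the brute-force N50 oracle", {
  s <- assembly_stats(c(10, 6, 5, 4, 2))
  expect_equal(s$total_bp, 27)
  expect_equal(s$largest_bp, 10)
  expect_equal(s$n50_bp, 6)
  expect_equal(assembly_stats(numeric(0))$n_contigs, 0)
  expect_equal(assembly_stats(42)$n50_bp, 42)
  set.seed(209)
  for (i in 1:200) {
    lens <- sample(1:5000, sample(1:40, 1), replace = TRUE)
    st <- assembly_stats(lens)
    expect_equal(st$n50_bp, oracle_n50(lens))
    expect_lte(st$n50_bp, st$largest_bp)
    expect_lte(st$largest_bp, st$total_bp)
  }
})
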