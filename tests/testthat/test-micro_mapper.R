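test_that("k-mer indexing honours window counts and N exclusion", {
  expect_warning(seq_index(c(t1 = "ACGTACGT"), k = 11), "shorter than k")
  s <- random_seq(100)
  idx <- seq_index(setNames(s, "t"), k = 21)
  expect_equal(gapfillr:::cpp_index_kmer_count(idx$ptr, 0L), 80)
  sN <- paste0(substr(s, 1, 40), "N", substr(s, 42, 100))
  idxN <- seq_index(setNames(sN, "t"), k = 21)
  # every window covering the N at 0-based 40 disappears: positions 20..40
  expect_equal(gapfillr:::cpp_index_kmer_count(idxN$ptr, 0L), 80 - 21)
})

test_that("exact unique reads map to their locus with high mapq; ambiguity gives mapq 0", {
  set.seed(101)
  ref <- random_seq(30000)
  idx <- seq_index(c(chr1 = ref))
  starts <- sample(1:(30000 - 100), 100)
  reads <- setNames(substring(ref, starts, starts + 99),
                    sprintf("r%03d", 1:100))
  aln <- map_reads(idx, reads)
  expect_true(all(aln$mapped))
  expect_true(all(aln$pos == starts - 1))
  expect_true(all(aln$mapq >= 30))
  # duplicated block -> ambiguous
  ref2 <- paste0(ref, substr(ref, 5001, 5150))
  idx2 <- seq_index(c(chr1 = ref2))
  amb <- map_reads(idx2, setNames(substr(ref, 5021, 5120), "amb"))
  expect_equal(amb$mapq, 0)
  expect_gte(amb$n_candidates, 2)
  # random sequence: unmapped under the identity threshold
  rnd <- map_reads(idx, setNames(random_seq(100), "x"))
  expect_false(rnd$mapped)
})

test_that("mapping the reverse complement flips strand and preserves locus", {
  set.seed(103)
  ref <- random_seq(20000)
  idx <- seq_index(c(chr1 = ref))
  starts <- sample(1:(20000 - 100), 30)
  fw <- setNames(substring(ref, starts, starts + 99), sprintf("f%02d", 1:30))
  rc <- setNames(vapply(fw, oracle_revcomp, character(1)),
                 sprintf("r%02d", 1:30))
  af <- map_reads(idx, fw)
  ar <- map_reads(idx, rc)
  expect_equal(ar$pos, af$pos)
  expect_true(all(af$strand == "+") && all(ar$strand == "-"))
})

test_that("error-free reads from a repeat-free target are recovered at >= 99%", {
  set.seed(107)
  ref <- random_seq(100000)
  idx <- seq_index(c(chr1 = ref))
  n <- 1000
  starts <- sample(1:(100000 - 100), n, replace = TRUE)
  reads <- substring(ref, starts, starts + 99)
  flip <- runif(n) < 0.5
  reads[flip] <- vapply(reads[flip], oracle_revcomp, character(1))
  aln <- map_reads(idx, setNames(reads, sprintf("r%04d", 1:n)))
  correct <- aln$mapped & aln$pos == starts - 1
  expect_gte(mean(correct), 0.99)
  expect_true(all(aln$mapq[correct] >= 30))
})

test_that("local alignment agrees with the Smith-Waterman oracle and reports identity", {
  set.seed(109)
  for (i in 1:25) {
    q <- random_seq(sample(30:200, 1))
    t <- random_seq(sample(50:200, 1))
    if (i %% 3 == 0) {
      # plant a mutated copy of part of q inside t
      piece <- substr(q, 5, min(nchar(q), 120))
      pc <- strsplit(piece, "")[[1]]
      mut <- sample(length(pc), max(1, length(pc) %/% 25))
      pc[mut] <- vapply(pc[mut], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      t <- paste0(substr(t, 1, 20), paste(pc, collapse = ""),
                  substr(t, 21, nchar(t)))
    }
    h <- align_local(q, t, min_score = 1, max_hits = 1)
    sw <- oracle_sw_score(q, t)
    if (sw < 1) { expect_equal(nrow(h), 0); next }
    expect_equal(h$score[1], sw)
  }
  # worked identity examples
  t <- random_seq(300)
  exact <- align_local(substr(t, 101, 200), t)
  expect_equal(exact$identity[1], 1)
  expect_equal(exact$coverage[1], 1)
  q <- substr(t, 101, 200)
  substr(q, 50, 50) <- if (substr(q, 50, 50) == "A") "C" else "A"
  one_mm <- align_local(q, t)
  expect_equal(one_mm$identity[1], 0.99)
  expect_error(align_local("", t), "empty query")
})
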