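# Folding backends, MFEI arithmetic, the duplex walk (mismatch and
# asymmetric-bulge counting), locus seeding and hairpin verdicts.

test_that("designed hairpin folds with at least four pairs and negative
           energy on both backends", {
  for (be in c(if (fibermir:::has_rnafold()) "vienna", "bpmax")) {
    f <- fold_rna("GGGGAAAACCCC", backend = be)
    expect_lt(f$mfe, 0)
    expect_gte(sum(strsplit(f$structure, "")[[1]] == "("), 4L)
    expect_identical(nchar(f$structure), 12L)
  }
})

test_that("a homopolymer has no structure and fails the energy criterion", {
  f <- fold_rna(strrep("A", 50))
  expect_identical(f$mfe, 0)
  expect_identical(f$structure, strrep(".", 50))
  ev <- evaluate_hairpin(f$sequence, f$structure, f$mfe, 10L, 21L)
  expect_false(ev$verdict)
  expect_match(ev$failed_criteria, "mfe")
})

test_that("folding is deterministic and rejects bad alphabets", {
  set.seed(2)
  s <- random_dna(5L, 120L, 0.5)
  expect_identical(fold_rna(s), fold_rna(s))
  expect_error(fold_rna("ACGTNNNACGT"), "non-ACGU")
})

test_that("MFEI follows the defining arithmetic and flags the 0.85
           boundary inclusively", {
  expect_equal(mfei(-42.5, 100, 50), 0.85, tolerance = 1e-12)
  ev <- evaluate_hairpin(strrep("ACGT", 25), strrep(".", 100), -42.5,
                         10L, 21L)
  # gc of ACGT repeats is 50%
  expect_equal(ev$mfei, 0.85, tolerance = 1e-9)
  expect_true(ev$mfei_flag)
  expect_error(mfei(-10, 0, 50), "positive")
})

test_that("a perfect-complement duplex has no mismatches or bulges and a
           synthetic precursor pairs mature to star", {
  m <- "TGACAGAAGAGAGTGAGCACA"
  prec <- paste0(m, "GTCAGATTTCGATCTA", revcomp(m))
  f <- fold_rna(prec)
  pt <- pair_table(f$structure)
  feats <- duplex_features(pt, 1L, nchar(m))
  expect_identical(feats$arm, "5p")
  expect_identical(feats$duplex_mismatches, 0L)
  expect_identical(feats$asymmetric_bulges, 0L)
  # mature base i pairs a base inside the star segment
  star_lo <- nchar(m) + 17L
  expect_true(all(pt[1:nchar(m)] >= star_lo))
})

test_that("duplex walk agrees with the constructed-duplex oracle on 1000
           randomized structures", {
  set.seed(101)
  for (i in 1:1000) {
    tr <- make_duplex_structure(random_duplex_events(sample(2:8, 1L)),
                                loop_len = sample(3:8, 1L))
    feats <- duplex_features(pair_table(tr$structure), tr$mature_start,
                             tr$mature_end)
    expect_identical(feats$duplex_mismatches, tr$mismatches)
    expect_identical(feats$asymmetric_bulges, tr$bulges)
    expect_identical(feats$unpaired_mature, tr$unpaired_mature)
  }
})

test_that("three constructed asymmetric bulges fail the bulge criterion", {
  evs <- list(list(type = "match"), list(type = "match"),
              list(type = "mbulge", k = 2L), list(type = "match"),
              list(type = "sbulge", k = 1L), list(type = "match"),
              list(type = "mbulge", k = 1L), list(type = "match"),
              list(type = "match"))
  tr <- make_duplex_structure(evs)
  n <- nchar(tr$structure)
  ev <- evaluate_hairpin(strrep("AC", ceiling(n / 2)) |> substr(1, n),
                         tr$structure, -30, tr$mature_start - 1L,
                         tr$mature_end)
  expect_identical(ev$asymmetric_bulges, 3L)
  expect_match(ev$failed_criteria, "asymmetric_bulges")
})

test_that("seeding emits two windows per stack and honours min_stack", {
  chrlen <- c(chr1 = 10000L)
  hits <- data.frame(chrom = "chr1", start = 5000L, end = 5021L,
                     strand = "+", count = 50L,
                     sequence = strrep("A", 21))
  s <- seed_loci(hits, chrlen)
  expect_identical(nrow(s), 2L)
  expect_identical(s$win_start, c(5000L - 250L, 5000L - 20L))
  expect_identical(s$win_end, c(5021L + 20L, 5021L + 250L))
  hits$count <- 4L
  expect_identical(nrow(seed_loci(hits, chrlen)), 0L)
})

test_that("windows seeded on the tiny genome cover every embedded locus", {
  ts <- tiny_sim()
  nov <- tiny_novel()
  loci <- ts$gen$loci[ts$gen$loci$type == "novel", ]
  for (i in seq_len(nrow(loci))) {
    covered <- any(nov$candidates$chrom == loci$chrom[i] &
                     nov$candidates$win_start <= loci$start[i] &
                     nov$candidates$win_end >= loci$end[i])
    expect_true(covered, label = paste("locus", loci$locus_id[i], "covered"))
  }
  # and the calls recover the loci (checked in depth in the acceptance suite)
  expect_gte(nrow(nov$calls), nrow(loci) - 1L)
})

test_that("dominance strictly decreases when off-footprint reads appear", {
  m <- "TGACAGAAGAGAGTGAGCACA"
  prec <- paste0(strrep("T", 40), m, "GTCAGATTTCGATCTA", revcomp(m),
                 strrep("T", 40))
  f <- fold_rna(prec)
  on_fp <- data.frame(offset = 40L, length = 21L, count = 90L)
  off_fp <- rbind(on_fp, data.frame(offset = 0L, length = 21L, count = 10L))
  ev1 <- evaluate_hairpin(f$sequence, f$structure, f$mfe, 40L, 21L,
                          locus_reads = on_fp)
  ev2 <- evaluate_hairpin(f$sequence, f$structure, f$mfe, 40L, 21L,
                          locus_reads = off_fp)
  expect_identical(ev1$dominance, 1)
  expect_lt(ev2$dominance, ev1$dominance)
  expect_equal(ev2$dominance, 0.9)
})

test_that("MFEI of every evaluated candidate matches a one-line
           recomputation", {
  cand <- tiny_novel()$candidates
  recomputed <- 100 * abs(cand$mfe) / (cand$length * cand$gc_percent)
  expect_true(all(abs(cand$mfei - recomputed) < 1e-6, na.rm = TRUE))
})

test_that("the 5'-nucleotide-by-length summary cross-tabulates calls", {
  calls <- data.frame(mature_seq = c("TGACAGAAGAGAGTGAGCACA",
                                     "AGACAGAAGAGAGTGAGCACAACG",
                                     "TGACAGAAGAGAGTGAGCAC"))
  s <- novel_summary(calls)
  expect_identical(unname(s$table["Total", "Total"]), 3L)
  expect_identical(unname(s$table["U", "21"]), 1L)
  expect_identical(unname(s$table["A", "24"]), 1L)
  expect_equal(unname(s$first_nt_percent["U"]), 66.7)
  single <- novel_summary(data.frame(first_nt = "U", length = 21L))
  expect_identical(unname(single$table["U", "21"]), 1L)
  expect_identical(unname(single$table["Total", "Total"]), 1L)
})
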