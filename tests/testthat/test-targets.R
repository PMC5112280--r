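# Position-weighted miRNA:target scoring and the transcript scanner.

MIR <- "ACGTTCGTACGTACGGACGTG"   # position 5 = T, position 15 = G

test_that("perfect complement scores zero and coordinates are exact", {
  tr <- c(t1 = paste0(strrep("A", 50), revcomp(MIR), strrep("C", 50)))
  h <- scan_transcripts(c(m1 = MIR), tr)
  expect_identical(nrow(h), 1L)
  expect_identical(h$expectation, 0)
  expect_identical(h$start, 50L)
  expect_identical(h$end, 71L)
  expect_identical(h$states, strrep("|", 21))
})

test_that("G:U wobble costs 0.5 outside the seed and double inside it", {
  site <- revcomp(MIR)
  mirc <- strsplit(MIR, "")[[1]]
  wobble_at <- function(pos) {
    sc <- strsplit(site, "")[[1]]
    i <- 21L - pos + 1L
    sc[i] <- if (mirc[pos] == "G") "T" else "G"
    paste(sc, collapse = "")
  }
  expect_equal(score_duplex(MIR, wobble_at(15))$expectation, 0.5)
  expect_equal(score_duplex(MIR, wobble_at(5))$expectation, 1.0)
  expect_error(score_duplex("ACGTX", "ACGTA"), "non-nucleotide")
})

test_that("expectation is monotone: extra mismatches never lower it", {
  set.seed(21)
  for (i in 1:20) {
    mir <- random_dna(1L, 21L, 0.5)
    site <- revcomp(mir)
    e0 <- score_duplex(mir, site)$expectation
    pos <- sample(21L, 1L)
    sc <- strsplit(site, "")[[1]]
    sc[pos] <- sample(setdiff(c("A", "C", "G", "T"), sc[pos]), 1L)
    e1 <- score_duplex(mir, paste(sc, collapse = ""))$expectation
    expect_gte(e1, e0)
  }
})

test_that("duplex scoring is symmetric under complement swap for
           wobble-free schemes", {
  scheme <- duplex_scheme(seed_multiplier = 1)
  set.seed(22)
  for (i in 1:20) {
    mir <- random_dna(1L, 21L, 0.5)
    site <- revcomp(mir)
    sc <- strsplit(site, "")[[1]]
    mc <- strsplit(mir, "")[[1]]
    p <- sample(21L, 2L)
    # X:X self-pairs stay plain mismatches under complement swap (never
    # a wobble), keeping both orientations wobble-free
    sc[p] <- mc[22L - p]
    site2 <- paste(sc, collapse = "")
    a <- score_duplex(mir, site2, scheme)$expectation
    b <- score_duplex(revcomp(site2), revcomp(mir), scheme)$expectation
    expect_equal(a, b)
  }
})

test_that("gap-free scanner equals the exhaustive window oracle on a 5 kb
           transcript", {
  set.seed(23)
  tr <- random_dna(1L, 5000L, 0.45)
  site <- revcomp(MIR)
  substr(tr, 2001L, 2021L) <- site
  got <- scan_transcripts(c(m = MIR), c(t = tr), max_expectation = 5,
                          max_gaps = 0L)
  want <- oracle_scan_gapless(MIR, tr, 5)
  # the scanner deduplicates overlapping windows; every oracle hit must be
  # covered by a reported hit of expectation <= its own
  expect_true(all(got$expectation <= 5))
  for (r in seq_len(nrow(want))) {
    cover <- got$start < want$end[r] & got$end > want$start[r] &
      got$expectation <= want$expectation[r] + 1e-9
    expect_true(any(cover))
  }
  # the best hit agrees exactly
  expect_identical(min(got$expectation), min(want$expectation))
  expect_identical(got$start[which.min(got$expectation)],
                   want$start[which.min(want$expectation)])
})

test_that("planted seed-mismatch sites (expectation 2) are recovered at
           cutoff 3 and missed at 1.5", {
  set.seed(24)
  mirs <- setNames(random_dna(5L, 21L, 0.5), paste0("m", 1:5))
  trs <- character(0)
  for (i in seq_along(mirs)) {
    tr <- random_dna(1L, 1200L, 0.45)
    site <- revcomp(mirs[[i]])
    pos_m <- 8L                                 # miRNA position 8: seed
    j <- 21L - pos_m + 1L
    sc <- strsplit(site, "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    mir_b <- strsplit(mirs[[i]], "")[[1]][pos_m]
    # substitution that is neither a match nor a wobble
    bad <- setdiff(c("A", "C", "G", "T"),
                   c(comp[mir_b], if (mir_b == "G") "T",
                     if (mir_b == "T") "G", sc[j]))[1]
    sc[j] <- bad
    substr(tr, 501L, 521L) <- paste(sc, collapse = "")
    trs[paste0("t", i)] <- tr
  }
  h3 <- scan_transcripts(mirs, trs, max_expectation = 3)
  found <- vapply(seq_along(mirs), function(i) {
    any(h3$mirna_id == names(mirs)[i] &
          h3$transcript_id == paste0("t", i) & h3$start == 500L &
          abs(h3$expectation - 2) < 1e-9)
  }, TRUE)
  expect_true(all(found))
  h15 <- scan_transcripts(mirs, trs, max_expectation = 1.5)
  missed <- vapply(seq_along(mirs), function(i) {
    !any(h15$mirna_id == names(mirs)[i] &
           h15$transcript_id == paste0("t", i) & h15$start == 500L)
  }, TRUE)
  expect_true(all(missed))
})

test_that("every reported hit respects the cutoff on shuffled transcripts", {
  set.seed(25)
  trs <- setNames(random_dna(4L, 1500L, 0.45), paste0("s", 1:4))
  mir <- random_dna(1L, 21L, 0.5)
  h <- scan_transcripts(c(m = mir), trs, max_expectation = 3)
  expect_true(all(h$expectation <= 3))
})

test_that("target summary reproduces the mean-targets arithmetic", {
  hits <- data.frame(mirna_id = rep(c("a", "b"), c(3, 2)),
                     transcript_id = c("t1", "t2", "t2", "t1", "t3"))
  s <- target_summary(hits, mirna_ids = c("a", "b", "c"))
  # a-t2 is reported twice but counts once: 4 non-redundant pairs
  expect_identical(s$n_nonredundant_pairs, 4L)
  expect_identical(s$mean_targets_per_mirna, 2)
  expect_identical(s$no_target, "c")
  empty <- target_summary(hits[0, ])
  expect_identical(empty$mean_targets_per_mirna, 0)
  expect_identical(empty$n_nonredundant_pairs, 0L)
})

test_that("synthetic truth with exactly three targets per miRNA gives a
           mean of 3.0", {
  hits <- expand.grid(mirna_id = paste0("m", 1:6),
                      transcript_id = paste0("t", 1:3),
                      stringsAsFactors = FALSE)
  expect_identical(target_summary(hits)$mean_targets_per_mirna, 3)
})
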