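# Synthetic-data generator: determinism, conservation, ground-truth
# containment, and the statistical structure downstream stages assume.

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(class_mix = c(A = 0.5, B = 0.5, C = 0.1, D = 0)),
               "sum to 1")
  expect_error(sim_config(genome_length = 5000, n_known_loci = 30,
                          n_novel_loci = 30), "too short")
  expect_error(sim_config(mirna_fraction = 0.9, contaminant_fraction = 0.1,
                          junk_fraction = 0.05), "fractions")
})

test_that("embedded matures are recoverable from the genome at their
           recorded coordinates", {
  ts <- tiny_sim()
  g <- ts$gen$genome$chr1
  for (i in seq_len(nrow(ts$gen$loci))) {
    l <- ts$gen$loci[i, ]
    s <- substr(g, l$mature_start + 1L, l$mature_end)
    if (l$strand == "-") s <- revcomp(s)
    expect_identical(s, l$mature_seq)
    # precursor containment: mature and star are inside the locus interval
    prec <- substr(g, l$start + 1L, l$end)
    if (l$strand == "-") prec <- revcomp(prec)
    expect_identical(substr(prec, 1L, nchar(l$mature_seq)), l$mature_seq)
    expect_true(grepl(l$star_seq, prec, fixed = TRUE))
  }
})

test_that("identical seeds give byte-identical dataset files", {
  cfg <- sim_config(seed = 9L, genome_length = 5e4, n_known_loci = 4L,
                    n_novel_loci = 4L, reads_per_library = 2000L)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("libraries conserve the configured read count exactly", {
  ts <- tiny_sim()
  for (lib in ts$libs) {
    expect_identical(nrow(lib), ts$cfg$reads_per_library)
  }
})

test_that("class archetypes shape expected locus proportions", {
  aw <- archetype_weights()
  expect_true(all(diff(aw["A", ]) < 0))          # monotone decreasing
  expect_true(all(diff(aw["D", ]) > 0))          # monotone increasing
  expect_identical(unname(which.max(aw["B", ])), 2L)
  expect_true(which.max(aw["C", ]) %in% c(2L, 3L))
  expect_equal(unname(rowSums(aw)), rep(1, 4))
})

test_that("zero star mutations give a mismatch-free duplex when folded", {
  cfg <- sim_config(seed = 5L, genome_length = 5e4, n_known_loci = 0L,
                    n_novel_loci = 6L, star_mutation_range = c(0L, 0L))
  gen <- simulate_genome(cfg)
  for (i in seq_len(nrow(gen$loci))) {
    l <- gen$loci[i, ]
    prec <- substr(gen$genome$chr1, l$start + 1L, l$end)
    if (l$strand == "-") prec <- revcomp(prec)
    f <- fold_rna(prec)
    feats <- duplex_features(pair_table(f$structure), 1L,
                             nchar(l$mature_seq))
    expect_identical(feats$duplex_mismatches, 0L)
    expect_identical(feats$asymmetric_bulges, 0L)
  }
})

test_that("zero contaminant fraction yields no contaminant-class reads", {
  cfg <- sim_config(seed = 5L, genome_length = 5e4, n_known_loci = 3L,
                    n_novel_loci = 3L, reads_per_library = 1500L,
                    contaminant_fraction = 0)
  gen <- simulate_genome(cfg)
  libs <- simulate_libraries(cfg, gen)
  expect_false(any(grepl("^contaminant:", libs[[1]]$source)))
})

test_that("dinucleotide shuffle preserves dinucleotide counts", {
  set.seed(1)
  s <- random_dna(1L, 3000L, 0.45)
  sh <- dinucleotide_shuffle(s)
  dinuc <- function(x) {
    ch <- strsplit(x, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  expect_identical(nchar(sh), nchar(s))
  expect_identical(dinuc(sh), dinuc(s))
  expect_false(sh == s)
})

test_that("degenerate RACE probability puts every clone at the canonical
           position", {
  ts <- tiny_sim()
  val <- simulate_validation(ts$cfg, ts$gen, n_targets = 3L,
                             p_canonical = 1, n_clones = 10L)
  for (i in seq_len(nrow(val$targets))) {
    tg <- val$targets[i, ]
    cl <- val$race_clones[val$race_clones$target_id == tg$target_id, ]
    expect_identical(nrow(cl), 10L)
    expect_true(all(cl$five_prime_pos_1based == tg$canonical_pos_1based))
  }
})

test_that("a mismatch-free planted site scores expectation zero", {
  ts <- tiny_sim()
  val <- simulate_validation(ts$cfg, ts$gen, n_targets = 3L,
                             site_mismatches = 0L)
  for (i in seq_len(nrow(val$targets))) {
    tg <- val$targets[i, ]
    site <- substr(val$transcripts[[tg$target_id]], tg$site_start + 1L,
                   tg$site_end)
    expect_identical(score_duplex(tg$mirna_seq, site)$expectation, 0)
  }
})

test_that("requesting a target for a nonexistent locus is an error", {
  ts <- tiny_sim()
  expect_error(simulate_validation(ts$cfg, ts$gen,
                                   target_loci = "no-such-locus"),
               "no such miRNA locus")
})
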