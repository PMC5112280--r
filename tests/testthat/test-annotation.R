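# Contaminant classification, genome mapping, and the class-distribution
# (read-category) report.

test_that("contaminant priority order assigns the first matching class", {
  ref_r <- paste0("GGGG", "ACGTACGTACGTACGTACGTA", "GGGG")
  ref_t <- paste0("TTTT", "ACGTACGTACGTACGTACGTA", "TTTT")
  lib <- new_read_library("x", c("ACGTACGTACGTACGTACGTA",
                                 "CCCCCCCCCCCCCCCCCCCCC"), c(1L, 1L))
  ann <- classify_contaminants(lib, list(rRNA = ref_r, tRNA = ref_t))
  expect_identical(as.character(ann$annotation_class),
                   c("rRNA", "none"))
  expect_error(classify_contaminants(lib, list(rRNA = character(0))),
               "empty reference")
  expect_error(classify_contaminants(lib, list()), "at least one")
})

test_that("a known contaminant spike is recovered exactly", {
  ts <- tiny_sim()
  libs <- tiny_libraries()
  raw <- ts$libs[[1]]
  lib <- libs[[1]]
  for (cls in c("rRNA", "tRNA")) {
    spiked <- sum(raw$source == paste0("contaminant:", cls))
    reported <- sum(lib$counts[lib$annotation_class == cls])
    expect_identical(reported, spiked)
  }
})

test_that("embedded matures map to their ground-truth coordinates", {
  ts <- tiny_sim()
  loci <- ts$gen$loci
  lib <- new_read_library("m", unique(loci$mature_seq),
                          rep(1L, length(unique(loci$mature_seq))))
  lib <- map_to_genome(lib, ts$gen$genome)
  for (i in seq_len(nrow(loci))) {
    ri <- match(loci$mature_seq[i], lib$sequences)
    h <- lib$genome_hits[lib$genome_hits$read == ri, ]
    expect_true(any(h$start == loci$mature_start[i] &
                      h$end == loci$mature_end[i] &
                      h$strand == loci$strand[i]))
  }
})

test_that("reverse-complement reads hit the minus strand on the identical
           interval", {
  genome <- list(chr1 = "TTTTTAACCGTAGGCTTAGCAACTGTTTTT")
  read <- substr(genome$chr1, 6L, 26L)
  lib <- new_read_library("x", c(read, revcomp(read)), c(1L, 1L))
  lib <- map_to_genome(lib, genome)
  h <- lib$genome_hits
  expect_identical(h$start[h$read == 1 & h$strand == "+"],
                   h$start[h$read == 2 & h$strand == "-"])
  expect_identical(h$end[h$read == 1 & h$strand == "+"],
                   h$end[h$read == 2 & h$strand == "-"])
})

test_that("genome mapper equals the naive all-positions oracle", {
  set.seed(77)
  genome <- list(chr1 = random_dna(1L, 20000L, 0.45))
  # half genuine genome substrings (some repeated), half random reads
  pos <- sample(1000:18000, 150L)
  reads <- unique(c(substring(genome$chr1, pos, pos + 20L),
                    random_dna(150L, 21L, 0.5)))
  lib <- new_read_library("o", reads, rep(1L, length(reads)))
  lib <- map_to_genome(lib, genome)
  for (i in seq_along(lib$sequences)) {
    got <- lib$genome_hits[lib$genome_hits$read == i,
                           c("start", "end", "strand")]
    want <- oracle_find_all(lib$sequences[i], genome$chr1)
    o1 <- got[order(got$start, got$strand), ]
    o2 <- want[order(want$start, want$strand), ]
    expect_identical(unname(as.matrix(o1)), unname(as.matrix(o2)))
  }
})

test_that("mismatch-tolerant mapping finds near matches with their edit
           counts", {
  genome <- list(chr1 = paste0(strrep("T", 30),
                               "AACCGTAGGCTTAGCAACTGA", strrep("T", 30)))
  read <- "AACCGTAGGCATAGCAACTGA"   # one substitution
  lib <- new_read_library("x", read, 1L)
  lib0 <- map_to_genome(lib, genome, max_mismatch = 0L)
  expect_identical(nrow(lib0$genome_hits), 0L)
  lib1 <- map_to_genome(lib, genome, max_mismatch = 1L)
  expect_identical(lib1$genome_hits$start, 30L)
  expect_identical(lib1$genome_hits$mismatches, 1L)
})

test_that("class counts partition the library and percentages follow the
           printed-percent arithmetic", {
  libs <- tiny_libraries()
  tab <- class_distribution_table(libs)
  for (lab in names(libs)) {
    sub <- tab[tab$library == lab, ]
    clean <- sub$count[sub$class == "Clean reads"]
    parts <- sub$count[!sub$class %in% "Clean reads"]
    expect_identical(sum(parts), clean)
    expect_equal(sub$percent, class_percent(sub$count, clean))
  }
})

test_that("zero contaminants give 0.00 percent rows", {
  expect_identical(class_percent(0L, 1000L), 0)
  expect_identical(class_percent(c(0L, 5L), 1000L), c(0, 0.5))
})
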