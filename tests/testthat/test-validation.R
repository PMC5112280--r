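# RACE cleavage mapping, 2^-ddCt quantification, and profile correlation.

test_that("clones opposite miRNA position 10 give canonical fraction 1", {
  site <- list(start = 100L, end = 121L)
  clones <- data.frame(target_id = "t", clone_id = paste0("c", 1:10),
                       five_prime_pos_1based = rep(121L - 10L + 1L, 10))
  cm <- map_cleavage(clones, target_len = 500L, mirna_len = 21L,
                     site = site)
  expect_identical(cm$positions$position, 10L)
  expect_identical(cm$positions$fraction, 1)
  expect_identical(cm$canonical_fraction, 1)
})

test_that("clone fractions follow counts and always sum to one", {
  site <- list(start = 100L, end = 121L)
  pos <- c(rep(121L - 10L + 1L, 8), rep(121L - 12L + 1L, 3))
  clones <- data.frame(target_id = "t", clone_id = paste0("c", 1:11),
                       five_prime_pos_1based = pos)
  cm <- map_cleavage(clones, 500L, 21L, site)
  expect_equal(cm$positions$fraction[cm$positions$position == 10L], 8 / 11)
  expect_equal(cm$positions$fraction[cm$positions$position == 12L], 3 / 11)
  expect_equal(sum(cm$positions$fraction), 1, tolerance = 1e-9)
  expect_equal(cm$canonical_fraction, 8 / 11)
})

test_that("clones outside the flanked site are unmapped and out-of-range
           coordinates are an error", {
  site <- list(start = 100L, end = 121L)
  clones <- data.frame(target_id = "t", clone_id = c("a", "b"),
                       five_prime_pos_1based = c(111L, 400L))
  cm <- map_cleavage(clones, 500L, 21L, site, flank = 20L)
  expect_identical(cm$n_mapped, 1L)
  expect_identical(cm$n_unmapped, 1L)
  clones$five_prime_pos_1based[2] <- 900L
  expect_error(map_cleavage(clones, 500L, 21L, site), "outside transcript")
})

test_that("simulated RACE clones recover the canonical-fraction rate", {
  cfg <- sim_config(seed = 12L, genome_length = 6e4, n_known_loci = 4L,
                    n_novel_loci = 4L)
  gen <- simulate_genome(cfg)
  val <- simulate_validation(cfg, gen, n_targets = 2L, p_canonical = 0.7,
                             n_clones = 200L, site_mismatches = 0L)
  for (i in seq_len(nrow(val$targets))) {
    tg <- val$targets[i, ]
    site <- list(start = tg$site_start, end = tg$site_end)
    cm <- map_cleavage(
      val$race_clones[val$race_clones$target_id == tg$target_id, ],
      tg$transcript_length, nchar(tg$mirna_seq), site)
    # binomial 95% interval around 0.7 at n = 200 (canonical window 9-11
    # also catches scattered clones at 9 and 11, hence the upper slack)
    expect_gte(cm$canonical_fraction, 0.7 - 1.96 * sqrt(0.7 * 0.3 / 200))
    expect_lte(cm$canonical_fraction, 0.8 + 1.96 * sqrt(0.8 * 0.2 / 200))
  }
})

make_ct <- function(ct_map) {
  # ct_map: list(gene -> named vector of per-sample Ct)
  rows <- list()
  for (g in names(ct_map)) {
    for (s in names(ct_map[[g]])) {
      for (b in 1:3) {
        for (tech in 1:3) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, sample = s, bio_rep = b, tech_rep = tech,
            ct = ct_map[[g]][[s]])
        }
      }
    }
  }
  do.call(rbind, rows)
}

test_that("ddCt arithmetic: one cycle difference halves expression and the
           calibrator is unity", {
  ct <- make_ct(list(tgt = c(cal = 24, s2 = 25), ref = c(cal = 20, s2 = 20)))
  res <- ddct(ct, "ref", "cal")
  expect_equal(res$summary$rel_expr[res$summary$sample == "cal"], 1)
  expect_equal(res$summary$rel_expr[res$summary$sample == "s2"], 0.5)
})

test_that("ddCt is invariant to adding a constant to every Ct", {
  ct <- make_ct(list(tgt = c(a = 23.5, b = 26.1), ref = c(a = 19.8, b = 20.4)))
  r1 <- ddct(ct, "ref", "a")
  ct2 <- ct
  ct2$ct <- ct2$ct + 3.7
  r2 <- ddct(ct2, "ref", "a")
  expect_equal(r1$summary$rel_expr, r2$summary$rel_expr, tolerance = 1e-12)
})

test_that("missing reference measurements are a pairing error", {
  ct <- make_ct(list(tgt = c(a = 24, b = 25), ref = c(a = 20)))
  expect_error(ddct(ct, "ref", "a"), "missing reference")
  expect_error(ddct(ct, "nope", "a"), "absent")
})

test_that("noise-free simulated Ct tables recover the latent fold changes
           exactly", {
  cfg <- sim_config(seed = 13L, genome_length = 6e4, n_known_loci = 4L,
                    n_novel_loci = 4L)
  gen <- simulate_genome(cfg)
  val <- simulate_validation(cfg, gen, n_targets = 3L, anti_strength = 1,
                             ct_noise = c(bio = 0, tech = 0))
  res <- ddct(val$qpcr_ct, val$reference_gene, "5DPA")
  for (i in seq_len(nrow(val$targets))) {
    tg <- val$targets[i, ]
    got <- res$summary$rel_expr[res$summary$gene == tg$target_id]
    want <- tg$rel_expr_truth[[1]]
    expect_equal(got, unname(want), tolerance = 1e-9)
  }
})

test_that("correlation verdicts: inverse profiles, self-correlation, and
           zero-variance error", {
  expect_equal(correlate_profiles(1:4, 4:1)$r, -1)
  expect_true(correlate_profiles(1:4, 4:1)$anti_correlated)
  expect_equal(correlate_profiles(1:4, 1:4)$r, 1)
  expect_error(correlate_profiles(rep(1, 4), 1:4), "zero-variance")
  expect_error(correlate_profiles(1:4, 1:3), "equal length")
})

test_that("strongly anti-correlated simulated pairs give negative r in at
           least 95 percent of replicates", {
  neg <- 0L
  aw <- archetype_weights()
  set.seed(99)
  for (rep in 1:100) {
    w <- aw[sample(4L, 1L), ]
    e <- -0.9 * log2(w / mean(w)) + rnorm(4L, 0, 0.25)
    if (correlate_profiles(w, 2^e)$anti_correlated) neg <- neg + 1L
  }
  expect_gte(neg, 95L)
})
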