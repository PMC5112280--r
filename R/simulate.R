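# Seeded generator of every input the pipeline consumes: genome with
# embedded miRNA precursors, four developmental small-RNA FASTQ libraries,
# contaminant reference sets, target transcripts, RACE clone records and
# qPCR Ct tables -- all with ground truth for parameter-recovery tests.

#' Expression archetype weights across the four libraries
#'
#' Class A: monotone decreasing; B: peak at the second library; C: peak at
#' the third; D: monotone increasing.  Rows sum to 1.
#'
#' @return 4x4 numeric matrix, rows `A`--`D`.
#' @export
archetype_weights <- function() {
  m <- rbind(
    A = c(0.40, 0.30, 0.20, 0.10),
    B = c(0.15, 0.45, 0.25, 0.15),
    C = c(0.10, 0.20, 0.45, 0.25),
    D = c(0.10, 0.20, 0.30, 0.40)
  )
  m / rowSums(m)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator.  The seed fully
#' determines all outputs (genome, libraries, validation data).
#'
#' @param seed integer master seed.
#' @param genome_length genome size in nt.
#' @param gc_content background G+C fraction.
#' @param n_known_loci,n_novel_loci embedded precursor counts.
#' @param n_contaminant_refs named integer vector: reference sequences per
#'   contaminant class.
#' @param library_labels ordered library names (DPA stages).
#' @param reads_per_library reads emitted per library (exact).
#' @param class_mix fractions of loci per expression class A-D (sums to 1).
#' @param adaptor_3p,adaptor_5p adaptor sequences (the 5' adaptor is
#'   carried for provenance; emitted reads are 5'-trimmed as sequencers
#'   deliver them).
#' @param dispersion negative-binomial dispersion for locus counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param mature_length mature miRNA length.
#' @param loop_length_range hairpin loop length bounds.
#' @param star_mutation_range substitutions applied to the star arm.
#' @param star_overhang 2-nt Dicer-style star 3' overhang (0 disables).
#' @param mirna_fraction,contaminant_fraction,junk_fraction read fractions
#'   for miRNA-locus reads, contaminant fragments and unmappable junk; the
#'   remainder are random genome fragments.
#' @param contaminant_ref_length length of generated contaminant refs.
#' @param contaminant_class_weights sampling weights across classes.
#' @param fragment_length_weights named weights over insert lengths for
#'   background genome fragments, tuned so 20-24 nt reads dominate with a
#'   24-nt mode.
#' @return a `sim_config` list (validated).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 2e6,
                       gc_content = 0.42,
                       n_known_loci = 30L,
                       n_novel_loci = 20L,
                       n_contaminant_refs = c(rRNA = 4L, tRNA = 4L,
                                              snRNA = 3L, snoRNA = 3L,
                                              `repeat` = 3L),
                       library_labels = c("5DPA", "10DPA", "15DPA", "20DPA"),
                       reads_per_library = 200000L,
                       class_mix = c(A = 0.25, B = 0.25, C = 0.25, D = 0.25),
                       adaptor_3p = "TGGAATTCTCGGGTGCCAAGG",
                       adaptor_5p = "GTTCAGAGTTCTACAGTCCGACGATC",
                       dispersion = 0.1,
                       mature_length = 21L,
                       loop_length_range = c(15L, 60L),
                       star_mutation_range = c(0L, 3L),
                       star_overhang = 2L,
                       mirna_fraction = 0.12,
                       contaminant_fraction = 0.05,
                       junk_fraction = 0.03,
                       contaminant_ref_length = 120L,
                       contaminant_class_weights = c(rRNA = 0.70,
                                                     tRNA = 0.15,
                                                     snRNA = 0.03,
                                                     snoRNA = 0.04,
                                                     `repeat` = 0.08),
                       fragment_length_weights = c(`18` = 0.01, `19` = 0.01,
                                                   `20` = 0.07, `21` = 0.12,
                                                   `22` = 0.11, `23` = 0.22,
                                                   `24` = 0.40, `25` = 0.03,
                                                   `26` = 0.01, `27` = 0.01,
                                                   `28` = 0.01)) {
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              gc_content = gc_content, n_known_loci = as.integer(n_known_loci),
              n_novel_loci = as.integer(n_novel_loci),
              n_contaminant_refs = n_contaminant_refs,
              library_labels = library_labels,
              reads_per_library = as.integer(reads_per_library),
              class_mix = class_mix, adaptor_3p = as_dna(adaptor_3p),
              adaptor_5p = as_dna(adaptor_5p), dispersion = dispersion,
              mature_length = as.integer(mature_length),
              loop_length_range = as.integer(loop_length_range),
              star_mutation_range = as.integer(star_mutation_range),
              star_overhang = as.integer(star_overhang),
              mirna_fraction = mirna_fraction,
              contaminant_fraction = contaminant_fraction,
              junk_fraction = junk_fraction,
              contaminant_ref_length = as.integer(contaminant_ref_length),
              contaminant_class_weights = contaminant_class_weights,
              fragment_length_weights = fragment_length_weights)
  if (abs(sum(cfg$class_mix) - 1) > 1e-9) stopf("class_mix must sum to 1")
  if (!setequal(names(cfg$class_mix), c("A", "B", "C", "D"))) {
    stopf("class_mix must be named A-D")
  }
  n_loci <- cfg$n_known_loci + cfg$n_novel_loci
  footprint <- n_loci * (2L * cfg$mature_length + cfg$loop_length_range[2] +
                           cfg$star_overhang)
  if (cfg$genome_length < 10 * footprint) {
    stopf("genome_length %g too short for %d loci (needs >= %g)",
          cfg$genome_length, n_loci, 10 * footprint)
  }
  if (cfg$mirna_fraction + cfg$contaminant_fraction + cfg$junk_fraction >= 1) {
    stopf("read fractions must leave room for genome fragments")
  }
  class(cfg) <- "sim_config"
  cfg
}

# family pool used for the embedded "known" loci
KNOWN_FAMILY_POOL <- c("miR156", "miR166", "miR169", "miR482", "miR157",
                       "miR160", "miR164", "miR167", "miR390", "miR399",
                       "miR396", "miR397", "miR398", "miR2950", "miR7505")

#' Simulate a genome with embedded miRNA precursors
#'
#' Builds a random background genome and embeds `n_known + n_novel`
#' precursors, each constructed as mature + loop + mutated
#' reverse-complement star + unpaired 3' overhang, on a random strand with
#' generous flanks.  Known loci are additionally emitted as a mature-miRNA
#' reference with family-structured identifiers.
#'
#' @param cfg a [sim_config()].
#' @return list: `genome` (named list of chromosome sequences), `loci`
#'   (ground-truth data.frame, 0-based half-open coordinates), `mature_ref`
#'   and `hairpin_ref` (named character, known loci only),
#'   `contaminant_refs` (named list per class).
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_loci <- cfg$n_known_loci + cfg$n_novel_loci
  slot_w <- 600L
  margin <- 400L
  n_slots <- floor((cfg$genome_length - 2 * margin) / slot_w)
  if (n_slots < n_loci) {
    stopf("genome of %g nt cannot host %d loci", cfg$genome_length, n_loci)
  }
  genome <- random_dna(1L, cfg$genome_length, cfg$gc_content)
  slots <- sort(sample.int(n_slots, n_loci))
  starts <- margin + (slots - 1L) * slot_w +
    sample.int(100L, n_loci, replace = TRUE)

  families <- sample(KNOWN_FAMILY_POOL, cfg$n_known_loci, replace = TRUE)
  fam_seen <- integer(0)
  loci <- vector("list", n_loci)
  classes <- sample(names(cfg$class_mix), n_loci, replace = TRUE,
                    prob = cfg$class_mix)
  for (i in seq_len(n_loci)) {
    m <- random_dna(1L, cfg$mature_length, 0.5)
    loop_len <- sample_range(cfg$loop_length_range)
    loop <- random_dna(1L, loop_len, cfg$gc_content)
    n_mut <- sample_range(cfg$star_mutation_range)
    star <- mutate_seq(revcomp(m), n_mut)
    overhang <- if (cfg$star_overhang > 0L) {
      random_dna(1L, cfg$star_overhang, 0.5)
    } else {
      ""
    }
    prec <- paste0(m, loop, star, overhang)
    strand <- sample(c("+", "-"), 1L)
    s0 <- starts[i]
    e0 <- s0 + nchar(prec)
    insert <- if (strand == "+") prec else revcomp(prec)
    substr(genome, s0 + 1L, e0) <- insert
    if (i <= cfg$n_known_loci) {
      fam <- families[i]
      fam_seen[fam] <- if (is.na(fam_seen[fam])) 1L else fam_seen[fam] + 1L
      id <- sprintf("%s%s", fam, letters[fam_seen[fam]])
      type <- "known"
    } else {
      fam <- NA_character_
      id <- sprintf("locus-n%02d", i - cfg$n_known_loci)
      type <- "novel"
    }
    mat0 <- if (strand == "+") s0 else e0 - cfg$mature_length
    loci[[i]] <- data.frame(
      locus_id = id, type = type, family = fam, chrom = "chr1",
      start = s0, end = e0, strand = strand,
      mature_start = mat0, mature_end = mat0 + cfg$mature_length,
      mature_seq = m, star_seq = star, loop_len = loop_len,
      star_mutations = n_mut, class = classes[i],
      stringsAsFactors = FALSE
    )
  }
  loci <- do.call(rbind, loci)
  known_idx <- which(loci$type == "known")
  mature_ref <- setNames(loci$mature_seq[known_idx], loci$locus_id[known_idx])
  hairpin_ref <- setNames(vapply(known_idx, function(i) {
    s <- substr(genome, loci$start[i] + 1L, loci$end[i])
    if (loci$strand[i] == "-") revcomp(s) else s
  }, ""), loci$locus_id[known_idx])
  contaminant_refs <- lapply(cfg$n_contaminant_refs, function(n) {
    setNames(random_dna(n, cfg$contaminant_ref_length, cfg$gc_content),
             paste0("ref", seq_len(n)))
  })
  list(genome = list(chr1 = genome), loci = loci, mature_ref = mature_ref,
       hairpin_ref = hairpin_ref, contaminant_refs = contaminant_refs)
}

#' Simulate the four raw small-RNA FASTQ libraries
#'
#' Reads are a mixture of (i) miRNA-locus reads whose per-library expected
#' proportions follow the locus's class archetype, with negative-binomial
#' count noise, (ii) contaminant fragments, (iii) random genome fragments
#' and (iv) unmappable junk; every read carries the 3' adaptor and a
#' constant high-quality string.  Exactly `reads_per_library` reads are
#' emitted per library.
#'
#' @param cfg a [sim_config()].
#' @param truth output of [simulate_genome()].
#' @return list per library label: data.frame with `id`, `insert`,
#'   `sequence` (adaptor-ligated), `quality`, `source`; plus attribute
#'   `locus_counts` (matrix loci x libraries of emitted locus reads).
#' @export
simulate_libraries <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  aw <- archetype_weights()
  loci <- truth$loci
  genome <- truth$genome$chr1
  nlib <- length(cfg$library_labels)
  N <- cfg$reads_per_library
  locus_counts <- matrix(0L, nrow = nrow(loci), ncol = nlib,
                         dimnames = list(loci$locus_id, cfg$library_labels))
  out <- setNames(vector("list", nlib), cfg$library_labels)
  frag_lens <- as.integer(names(cfg$fragment_length_weights))
  cls_w <- cfg$contaminant_class_weights
  cls_w <- cls_w[names(cls_w) %in% names(truth$contaminant_refs)]

  for (l in seq_len(nlib)) {
    n_mirna <- round(N * cfg$mirna_fraction)
    n_cont <- round(N * cfg$contaminant_fraction)
    n_junk <- round(N * cfg$junk_fraction)

    w <- aw[loci$class, l]
    mu <- n_mirna * w / sum(w)
    counts <- if (cfg$dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
    } else {
      stats::rpois(length(mu), mu)
    }
    allowed <- N - n_cont - n_junk
    if (sum(counts) > allowed) {
      counts <- floor(counts * allowed / sum(counts))
    }
    locus_counts[, l] <- counts

    mir <- vector("list", nrow(loci))
    for (i in seq_len(nrow(loci))) {
      if (counts[i] == 0L) next
      mseq <- loci$mature_seq[i]
      # 3'-templated length variants and star reads
      nv <- drop(stats::rmultinom(1L, counts[i],
                                  c(exact = 0.80, plus1 = 0.08,
                                    minus1 = 0.04, star = 0.08)))
      nxt <- if (loci$strand[i] == "+") {
        substr(genome, loci$mature_end[i] + 1L, loci$mature_end[i] + 1L)
      } else {
        revcomp(substr(genome, loci$mature_start[i], loci$mature_start[i]))
      }
      reads <- c(rep(mseq, nv["exact"]),
                 rep(paste0(mseq, nxt), nv["plus1"]),
                 rep(substr(mseq, 1L, nchar(mseq) - 1L), nv["minus1"]),
                 rep(loci$star_seq[i], nv["star"]))
      mir[[i]] <- data.frame(insert = reads,
                             source = loci$locus_id[i],
                             stringsAsFactors = FALSE)
    }
    mir <- do.call(rbind, mir)

    cont <- NULL
    if (n_cont > 0L) {
      cls <- sample(names(cls_w), n_cont, replace = TRUE, prob = cls_w)
      ins <- character(n_cont)
      for (j in seq_len(n_cont)) {
        refs <- truth$contaminant_refs[[cls[j]]]
        r <- refs[[sample.int(length(refs), 1L)]]
        len <- sample(20:24, 1L)
        s <- sample.int(nchar(r) - len + 1L, 1L)
        ins[j] <- substr(r, s, s + len - 1L)
      }
      cont <- data.frame(insert = ins, source = paste0("contaminant:", cls),
                         stringsAsFactors = FALSE)
    }

    junk <- if (n_junk > 0L) {
      data.frame(insert = random_dna(n_junk, sample(20:24, n_junk,
                                                    replace = TRUE), 0.5),
                 source = "junk", stringsAsFactors = FALSE)
    } else {
      NULL
    }

    n_frag <- N - nrow_or0(mir) - n_cont - n_junk
    frag <- NULL
    if (n_frag > 0L) {
      len <- sample(frag_lens, n_frag, replace = TRUE,
                    prob = cfg$fragment_length_weights)
      pos <- sample.int(nchar(genome) - max(len), n_frag, replace = TRUE)
      ins <- substring(genome, pos, pos + len - 1L)
      minus <- sample(c(TRUE, FALSE), n_frag, replace = TRUE)
      ins[minus] <- revcomp(ins[minus])
      frag <- data.frame(insert = ins, source = "fragment",
                         stringsAsFactors = FALSE)
    }

    reads <- rbind(mir, cont, junk, frag)
    reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
    reads$id <- sprintf("%s_read%07d", cfg$library_labels[l],
                        seq_len(nrow(reads)))
    reads$sequence <- paste0(reads$insert, cfg$adaptor_3p)
    reads$quality <- strrep("I", nchar(reads$sequence))
    rownames(reads) <- NULL
    out[[l]] <- reads[, c("id", "insert", "sequence", "quality", "source")]
  }
  attr(out, "locus_counts") <- locus_counts
  out
}

nrow_or0 <- function(x) if (is.null(x)) 0L else nrow(x)

# uniform draw from an inclusive integer range, robust to lo == hi
sample_range <- function(range) {
  if (range[1] >= range[2]) return(range[1])
  range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L
}

#' Write simulated libraries as FASTQ files
#'
#' @param libs output of [simulate_libraries()].
#' @param dir output directory.
#' @return named vector of file paths.
#' @export
write_fastq_libraries <- function(libs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (label in names(libs)) {
    df <- libs[[label]]
    path <- file.path(dir, paste0("lib_", label, ".fastq"))
    writeLines(as.vector(rbind(paste0("@", df$id), df$sequence, "+",
                               df$quality)), path)
    paths[label] <- path
  }
  paths
}

#' Simulate target transcripts, RACE clones and qPCR Ct tables
#'
#' For a selection of embedded miRNA loci, builds transcripts embedding a
#' near-complementary site, RACE clone 5' ends concentrated opposite miRNA
#' positions 10 (probability `p_canonical`) and scattered elsewhere, and a
#' Ct table (target + reference gene, samples x biological x technical
#' replicates) whose latent target expression is anti-correlated with the
#' miRNA's class archetype.
#'
#' @param cfg a [sim_config()].
#' @param truth output of [simulate_genome()].
#' @param target_loci locus identifiers to target (default: a deterministic
#'   mix of known and novel loci); unknown identifiers are an error.
#' @param n_targets number of targets when `target_loci` is NULL.
#' @param site_mismatches,site_gu substitutions / G:U wobbles planted in
#'   each site.
#' @param p_canonical probability a RACE clone ends at the canonical
#'   position (opposite miRNA base 10).
#' @param n_clones RACE clones per target.
#' @param anti_strength anti-correlation strength between miRNA archetype
#'   and target expression (1 = exact inverse).
#' @param ct_noise named vector `bio`/`tech`: SDs of Ct noise (0 = exact).
#' @param transcript_length_range transcript length bounds.
#' @return list: `transcripts` (named character), `race_clones`
#'   (data.frame `target_id`, `clone_id`, `five_prime_pos_1based`),
#'   `qpcr_ct` (data.frame `gene`, `sample`, `bio_rep`, `tech_rep`, `ct`),
#'   `targets` (truth: site coordinates, canonical positions, latent
#'   relative-expression profiles), `reference_gene`.
#' @export
simulate_validation <- function(cfg, truth, target_loci = NULL,
                                n_targets = 9L, site_mismatches = 1L,
                                site_gu = 0L, p_canonical = 0.7,
                                n_clones = 20L, anti_strength = 0.9,
                                ct_noise = c(bio = 0.15, tech = 0.05),
                                transcript_length_range = c(500L, 1500L)) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  loci <- truth$loci
  if (is.null(target_loci)) {
    n_targets <- min(n_targets, nrow(loci))
    target_loci <- loci$locus_id[round(seq(1L, nrow(loci),
                                           length.out = n_targets))]
  }
  missing_ids <- setdiff(target_loci, loci$locus_id)
  if (length(missing_ids)) {
    stopf("no such miRNA locus: %s", paste(missing_ids, collapse = ", "))
  }
  aw <- archetype_weights()
  transcripts <- character(0)
  targets <- list()
  race <- list()
  ct_rows <- list()
  ref_gene <- "UBQ10"
  nlib <- length(cfg$library_labels)

  for (t in seq_along(target_loci)) {
    li <- which(loci$locus_id == target_loci[t])
    mseq <- loci$mature_seq[li]
    m <- nchar(mseq)
    tid <- sprintf("TC%06d", 200000L + t)
    tlen <- sample_range(transcript_length_range)
    site <- revcomp(mseq)
    if (site_gu > 0L) {
      # miRNA G : site U wobble -- flip site C (pairing a miRNA G) to T
      cpos <- which(strsplit(site, "")[[1]] == "C")
      flip <- head(sample(cpos), site_gu)
      for (fp in flip) substr(site, fp, fp) <- "T"
    }
    site <- mutate_seq(site, site_mismatches)
    s0 <- sample(seq(100L, tlen - 100L - m), 1L)
    tr <- random_dna(1L, tlen, cfg$gc_content)
    substr(tr, s0 + 1L, s0 + m) <- site
    transcripts[tid] <- tr
    site_end <- s0 + m

    canonical_pos <- site_end - 10L + 1L   # 1-based transcript coordinate
    is_can <- runif(n_clones) < p_canonical
    p_rel <- ifelse(is_can, 10L,
                    sample(setdiff(seq_len(m), 10L), n_clones,
                           replace = TRUE))
    clone_pos <- site_end - p_rel + 1L
    race[[t]] <- data.frame(
      target_id = tid,
      clone_id = sprintf("%s_clone%03d", tid, seq_len(n_clones)),
      five_prime_pos_1based = as.integer(clone_pos),
      stringsAsFactors = FALSE
    )

    w <- aw[loci$class[li], ]
    e <- -anti_strength * log2(w / mean(w))   # latent log2 target level
    gene <- tid
    for (s in seq_len(nlib)) {
      for (b in 1:3) {
        e_b <- e[s] + rnorm(1L, 0, ct_noise[["bio"]])
        ref_b <- 20 + rnorm(1L, 0, ct_noise[["bio"]])
        for (tech in 1:3) {
          ct_rows[[length(ct_rows) + 1L]] <- data.frame(
            gene = c(gene, ref_gene),
            sample = cfg$library_labels[s],
            bio_rep = b, tech_rep = tech,
            ct = c(24 - e_b + rnorm(1L, 0, ct_noise[["tech"]]),
                   ref_b + rnorm(1L, 0, ct_noise[["tech"]])),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    targets[[t]] <- data.frame(
      target_id = tid, mirna_id = loci$locus_id[li],
      mirna_seq = mseq, class = loci$class[li],
      transcript_length = tlen, site_start = s0, site_end = site_end,
      canonical_pos_1based = canonical_pos,
      stringsAsFactors = FALSE
    )
    targets[[t]]$rel_expr_truth <- I(list(2^(e - e[1])))
  }
  list(transcripts = transcripts,
       race_clones = do.call(rbind, race),
       qpcr_ct = do.call(rbind, ct_rows),
       targets = do.call(rbind, targets),
       reference_gene = ref_gene)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs [simulate_genome()], [simulate_libraries()] and
#' [simulate_validation()] under the configured seed and writes
#' `genome.fa`, `mature_ref.fa`, `contaminant_<class>.fa`,
#' `lib_<label>.fastq`, `transcripts.fa`, `race_clones.tsv`,
#' `qpcr_ct.tsv` and `truth.json` into `out_dir`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created).
#' @return (invisibly) list with the in-memory objects and file `paths`.
#' @export
simulate_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- simulate_genome(cfg)
  libs <- simulate_libraries(cfg, gen)
  val <- simulate_validation(cfg, gen)
  paths <- c(
    genome = file.path(out_dir, "genome.fa"),
    mature_ref = file.path(out_dir, "mature_ref.fa"),
    hairpin_ref = file.path(out_dir, "hairpin_ref.fa"),
    transcripts = file.path(out_dir, "transcripts.fa"),
    race_clones = file.path(out_dir, "race_clones.tsv"),
    qpcr_ct = file.path(out_dir, "qpcr_ct.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_fasta(unlist(gen$genome), paths["genome"])
  write_fasta(gen$mature_ref, paths["mature_ref"])
  write_fasta(gen$hairpin_ref, paths["hairpin_ref"])
  for (cls in names(gen$contaminant_refs)) {
    p <- file.path(out_dir, paste0("contaminant_", cls, ".fa"))
    write_fasta(setNames(gen$contaminant_refs[[cls]],
                         paste0(cls, "_", names(gen$contaminant_refs[[cls]]))),
                p)
    paths[paste0("contaminant_", cls)] <- p
  }
  fq <- write_fastq_libraries(libs, out_dir)
  paths[paste0("lib_", names(fq))] <- fq
  write_fasta(val$transcripts, paths["transcripts"])
  write_tsv(val$race_clones, paths["race_clones"])
  write_tsv(val$qpcr_ct, paths["qpcr_ct"])
  truth_json <- list(
    loci = gen$loci,
    locus_counts = as.data.frame(attr(libs, "locus_counts")),
    targets = val$targets[, setdiff(names(val$targets), "rel_expr_truth")],
    reference_gene = val$reference_gene
  )
  jsonlite::write_json(truth_json, paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(list(config = cfg, genome = gen, libraries = libs,
                 validation = val, paths = paths))
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson Euler-path shuffle: the returned sequence has exactly
#' the original dinucleotide counts, destroying longer-range structure such
#' as embedded hairpins.  Used for empirical false-discovery control.
#'
#' @param seq a single sequence.
#' @return shuffled sequence of the same length.
#' @export
dinucleotide_shuffle <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 3L) return(seq)
  verts <- sort(unique(ch))
  K <- length(verts)
  vi <- match(ch, verts)
  final <- vi[n]
  edges <- vector("list", K)
  for (v in seq_len(K)) edges[[v]] <- vi[-1][vi[-n] == v]
  has_out <- vapply(edges, length, 0L) > 0L
  repeat {
    pick <- rep(NA_integer_, K)
    for (v in seq_len(K)) {
      if (has_out[v]) {
        pick[v] <- edges[[v]][sample.int(length(edges[[v]]), 1L)]
      }
    }
    ok <- TRUE
    for (v in seq_len(K)) {
      if (!has_out[v] || v == final) next
      cur <- v
      for (step in seq_len(K + 1L)) {
        if (cur == final) break
        cur <- pick[cur]
        if (is.na(cur)) break
      }
      if (is.na(cur) || cur != final) {
        ok <- FALSE
        break
      }
    }
    if (ok) break
  }
  ordered <- vector("list", K)
  for (v in seq_len(K)) {
    e <- edges[[v]]
    if (!length(e)) next
    if (v == final) {
      ordered[[v]] <- e[sample.int(length(e))]
    } else {
      i <- which(e == pick[v])[1]
      rest <- e[-i]
      ordered[[v]] <- c(rest[sample.int(length(rest))], pick[v])
    }
  }
  ptr <- rep(1L, K)
  out <- integer(n)
  out[1] <- vi[1]
  cur <- vi[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(verts[out], collapse = "")
}
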