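# Independent oracles used to cross-check the package implementations.

# All (overlapping) occurrences of `read` in `genome` on both strands via
# repeated naive string search; returns 0-based half-open intervals.
oracle_find_all <- function(read, genome) {
  one_strand <- function(pat, strand) {
    out <- NULL
    from <- 1L
    repeat {
      hit <- regexpr(pat, substr(genome, from, nchar(genome)), fixed = TRUE)
      if (hit < 0L) break
      s <- from + as.integer(hit) - 1L
      out <- rbind(out, data.frame(start = s - 1L,
                                   end = s - 1L + nchar(pat),
                                   strand = strand))
      from <- s + 1L
    }
    out
  }
  res <- rbind(one_strand(read, "+"), one_strand(revcomp(read), "-"))
  if (is.null(res)) {
    data.frame(start = integer(0), end = integer(0), strand = character(0))
  } else {
    res
  }
}

# Exhaustive gap-free window scoring of a miRNA against a transcript.
oracle_scan_gapless <- function(mirna, transcript, cutoff,
                                scheme = duplex_scheme()) {
  m <- nchar(mirna)
  out <- NULL
  for (s in seq_len(nchar(transcript) - m + 1L)) {
    e <- score_duplex(mirna, substr(transcript, s, s + m - 1L),
                      scheme)$expectation
    if (e <= cutoff) {
      out <- rbind(out, data.frame(start = s - 1L, end = s - 1L + m,
                                   expectation = e))
    }
  }
  if (is.null(out)) {
    data.frame(start = integer(0), end = integer(0), expectation = numeric(0))
  } else {
    out
  }
}

# Construct a hairpin whose duplex composition is known by construction:
# a sequence of events (match / symmetric mismatch run / mature-side bulge /
# star-side bulge), always separated by matches so maximal runs coincide
# with events.  Returns the dot-bracket string, the mature span (the whole
# left arm) and the true mismatch/bulge counts.
make_duplex_structure <- function(events, loop_len = 4L) {
  left <- character(0)
  right <- character(0)   # in left-arm event order; reversed at the end
  mismatches <- 0L
  bulges <- 0L
  unpaired_mature <- 0L
  for (ev in events) {
    if (ev$type == "match") {
      left <- c(left, "(")
      right <- c(right, ")")
    } else if (ev$type == "mismatch") {
      left <- c(left, rep(".", ev$k))
      right <- c(right, rep(".", ev$k))
      mismatches <- mismatches + ev$k
      unpaired_mature <- unpaired_mature + ev$k
    } else if (ev$type == "mbulge") {
      left <- c(left, rep(".", ev$k))
      bulges <- bulges + 1L
      unpaired_mature <- unpaired_mature + ev$k
    } else if (ev$type == "sbulge") {
      right <- c(right, rep(".", ev$k))
      bulges <- bulges + 1L
    } else {
      stop("unknown event type")
    }
  }
  structure <- paste(c(left, rep(".", loop_len), rev(right)), collapse = "")
  list(structure = structure, mature_start = 1L,
       mature_end = length(left), mismatches = mismatches,
       bulges = bulges, unpaired_mature = unpaired_mature)
}

# random event list for the bulge-counter property; anchored by matches and
# with every non-match event separated by at least one match
random_duplex_events <- function(n_events) {
  evs <- list(list(type = "match"))
  for (i in seq_len(n_events)) {
    t <- sample(c("match", "mismatch", "mbulge", "sbulge"), 1L,
                prob = c(0.55, 0.2, 0.125, 0.125))
    if (t == "match") {
      evs[[length(evs) + 1L]] <- list(type = "match")
    } else {
      evs[[length(evs) + 1L]] <- list(type = t, k = sample(1:3, 1L))
      evs[[length(evs) + 1L]] <- list(type = "match")
    }
  }
  evs[[length(evs) + 1L]] <- list(type = "match")
  evs
}

# small simulated dataset shared by several tests; built once per file
tiny_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42L, genome_length = 6e4,
                        n_known_loci = 6L, n_novel_loci = 6L,
                        reads_per_library = 6000L)
      gen <- simulate_genome(cfg)
      libs <- simulate_libraries(cfg, gen)
      cache <<- list(cfg = cfg, gen = gen, libs = libs)
    }
    cache
  }
})

# novel-miRNA prediction on the tiny dataset (known reads excluded)
tiny_novel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ts <- tiny_sim()
      counts <- merge_libraries(tiny_libraries())
      res <- assign_known(counts, ts$gen$mature_ref)
      cache <<- predict_novel(res$unassigned, ts$gen$genome,
                              exclude_hairpins = ts$gen$hairpin_ref)
    }
    cache
  }
})

# cleaned + annotated ReadLibrary objects for the tiny dataset
tiny_libraries <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ts <- tiny_sim()
      dir <- file.path(tempdir(), "fibermir-tiny-fq")
      paths <- write_fastq_libraries(ts$libs, dir)
      libs <- lapply(names(paths), function(label) {
        lib <- clean_reads(paths[[label]], ts$cfg$adaptor_3p,
                           min_len = 18L, max_len = 44L, label = label)
        lib <- subset_lengths(lib, 18L, 28L)
        lib <- classify_contaminants(lib, ts$gen$contaminant_refs)
        map_to_genome(lib, ts$gen$genome)
      })
      names(libs) <- names(paths)
      cache <<- libs
    }
    cache
  }
})
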