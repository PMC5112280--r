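# End-to-end orchestration: declarative configuration, staged execution
# with per-stage logging, and the survey-style report tables.

#' Default pipeline configuration
#'
#' One declarative list holding every stage parameter.  Unknown keys are
#' rejected when the configuration is validated, and the resolved
#' configuration is written beside the outputs of every run.
#'
#' @param seed master seed (also used by the simulate stage).
#' @return nested configuration list.
#' @export
pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "preprocess", "annotate", "known", "novel",
               "quantify", "cluster", "targets", "race", "qpcr", "report"),
    simulate = list(genome_length = 2e5, n_known_loci = 15L,
                    n_novel_loci = 15L, reads_per_library = 30000L),
    preprocess = list(min_len = 18L, max_len = 44L, analysis_min = 18L,
                      analysis_max = 28L, min_qual = 20L, min_overlap = 8L,
                      max_adaptor_mismatch = 1L),
    annotate = list(max_mismatch = 0L, max_hits = 20L),
    known = list(max_mismatch = 2L, length_variant_nt = 2L),
    novel = list(min_stack = 5L, window = 250L, merge_gap = 10L,
                 min_read_count = 2L, backend = "auto",
                 thresholds = novel_thresholds()),
    quantify = list(scale_factor = 1e7, min_rptm = 100),
    cluster = list(k = 4L, pseudocount = 1, distance = "euclidean"),
    targets = list(max_expectation = 3, max_gaps = 1L,
                   scheme = duplex_scheme()),
    race = list(flank = 20L),
    qpcr = list(calibrator = NULL)  # NULL = first library label
  )
}

validate_config <- function(config, template = pipeline_config()) {
  check <- function(cfg, tpl, path) {
    unknown <- setdiff(names(cfg), names(tpl))
    if (length(unknown)) {
      stopf("unknown configuration key(s): %s",
            paste(paste0(path, unknown), collapse = ", "))
    }
    for (k in names(cfg)) {
      if (is.list(tpl[[k]]) && !is.null(names(tpl[[k]])) && is.list(cfg[[k]])) {
        check(cfg[[k]], tpl[[k]], paste0(path, k, "."))
      }
    }
  }
  check(config, template, "")
  merged <- template
  for (k in names(config)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
        is.list(config[[k]])) {
      for (k2 in names(config[[k]])) merged[[k]][[k2]] <- config[[k]][[k2]]
    } else {
      merged[[k]] <- config[[k]]
    }
  }
  merged
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order (simulate, preprocess, annotate,
#' known, novel, quantify, cluster, targets, race, qpcr, report), each
#' stage consuming the previous stage's outputs, and writes deterministic
#' TSV/FASTA/GFF3 outputs plus the resolved configuration and a run log to
#' `out_dir`.
#'
#' @param config configuration list (see [pipeline_config()]); partial
#'   lists are merged over the defaults, unknown keys are an error.
#' @param out_dir output directory.
#' @return (invisibly) a list with all stage results.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  writeLines(character(0), log_path)
  yaml::write_yaml(cfg, file.path(out_dir, "run_config.yaml"))
  st <- function(s) s %in% cfg$stages
  res <- list(config = cfg)

  if (st("simulate")) {
    sim_args <- c(list(seed = cfg$seed), cfg$simulate)
    sim <- simulate_dataset(do.call(sim_config, sim_args),
                            file.path(out_dir, "sim"))
    res$sim <- sim
    logf("simulate: %d loci, %d reads x %d libraries",
         nrow(sim$genome$loci), sim$config$reads_per_library,
         length(sim$libraries))
  } else {
    stopf("run_pipeline currently requires the simulate stage to supply inputs")
  }

  if (!st("preprocess")) stopf("stage 'preprocess' required by later stages")
  pp <- cfg$preprocess
  fq <- res$sim$paths[grep("^lib_", names(res$sim$paths))]
  labels <- sub("^lib_", "", names(fq))
  libs <- mapply(function(path, label) {
    lib <- clean_reads(path, res$sim$config$adaptor_3p,
                       min_len = pp$min_len, max_len = pp$max_len,
                       min_qual = pp$min_qual, min_overlap = pp$min_overlap,
                       max_adaptor_mismatch = pp$max_adaptor_mismatch,
                       label = label)
    subset_lengths(lib, pp$analysis_min, pp$analysis_max)
  }, fq, labels, SIMPLIFY = FALSE)
  names(libs) <- labels
  for (lib in libs) {
    logf("preprocess %s: %d clean reads (%d unique)", lib$label,
         lib$total_clean_reads, length(lib$sequences))
    write_tsv(data.frame(sequence = lib$sequences, count = lib$counts),
              file.path(out_dir, paste0("collapsed_", lib$label, ".tsv")))
  }
  fig1 <- do.call(rbind, lapply(libs, function(lib) {
    d <- length_distribution(lib)
    cbind(library = lib$label, d)
  }))
  write_tsv(fig1, file.path(out_dir, "length_distribution.tsv"))
  res$libraries <- libs

  if (st("annotate")) {
    refs <- res$sim$genome$contaminant_refs
    # annotate the pooled unique sequences once, then distribute
    useq <- unique(unlist(lapply(libs, function(l) l$sequences)))
    pooled <- new_read_library("pooled", useq, rep(1L, length(useq)))
    pooled <- classify_contaminants(pooled, refs, cfg$annotate$max_mismatch)
    pooled <- map_to_genome(pooled, res$sim$genome$genome,
                            max_mismatch = cfg$annotate$max_mismatch,
                            max_hits = cfg$annotate$max_hits)
    libs <- lapply(libs, function(lib) {
      i <- match(lib$sequences, pooled$sequences)
      lib$annotation_class <- pooled$annotation_class[i]
      lib$genome_matched <- pooled$genome_matched[i]
      lib$multi_mapper <- pooled$multi_mapper[i]
      lib
    })
    res$libraries <- libs
    tab1 <- class_distribution_table(libs)
    write_tsv(tab1, file.path(out_dir, "class_distribution.tsv"))
    res$class_table <- tab1
    logf("annotate: class table written (%d rows)", nrow(tab1))
  }

  known <- NULL
  if (st("known")) {
    known <- assign_known(res$libraries, res$sim$genome$mature_ref,
                          max_mismatch = cfg$known$max_mismatch,
                          length_variant_nt = cfg$known$length_variant_nt)
    res$known <- known
    ktab <- do.call(rbind, lapply(known$calls, function(call) {
      data.frame(mirna_id = call$mirna_id, family = call$family,
                 canonical = call$canonical,
                 n_variants = nrow(call$variants),
                 t(call$totals), check.names = FALSE)
    }))
    if (!is.null(ktab)) {
      write_tsv(ktab, file.path(out_dir, "known_mirnas.tsv"))
    }
    write_tsv(family_summary(known$calls),
              file.path(out_dir, "known_families.tsv"))
    logf("known: %d calls, %d unassigned unique reads",
         length(known$calls), nrow(known$unassigned))
  }

  novel <- NULL
  if (st("novel")) {
    counts <- if (!is.null(known)) known$unassigned else
      merge_libraries(res$libraries)
    novel <- predict_novel(counts, res$sim$genome$genome,
                           thresholds = cfg$novel$thresholds,
                           min_stack = cfg$novel$min_stack,
                           window = cfg$novel$window,
                           merge_gap = cfg$novel$merge_gap,
                           min_read_count = cfg$novel$min_read_count,
                           backend = cfg$novel$backend,
                           exclude_hairpins = res$sim$genome$hairpin_ref)
    res$novel <- novel
    write_tsv(novel$candidates[, setdiff(names(novel$candidates),
                                         c("precursor_seq", "structure"))],
              file.path(out_dir, "hairpin_candidates.tsv"))
    if (nrow(novel$calls)) {
      write_fasta(setNames(novel$calls$precursor_seq, novel$calls$mirna_id),
                  file.path(out_dir, "novel_precursors.fa"))
      write_novel_gff3(novel$calls, file.path(out_dir, "novel_mirnas.gff3"))
      writeLines(unlist(lapply(seq_len(nrow(novel$calls)), function(i) {
        c(paste0(">", novel$calls$mirna_id[i]),
          as_rna(novel$calls$precursor_seq[i]),
          novel$calls$structure[i],
          sprintf("MFE %.2f kcal/mol  MFEI %.2f", novel$calls$mfe[i],
                  novel$calls$mfei[i]))
      })), file.path(out_dir, "novel_structures.txt"))
      tab2 <- novel_summary(novel$calls)
      write.table(tab2$table, file.path(out_dir, "novel_summary.tsv"),
                  sep = "\t", quote = FALSE, col.names = NA)
      res$table2 <- tab2
    }
    logf("novel: %d candidate windows, %d calls", nrow(novel$candidates),
         nrow(novel$calls))
  }

  expr <- NULL
  if (st("quantify")) {
    if (is.null(known) || is.null(novel)) {
      stopf("stage 'quantify' requires stages 'known' and 'novel'")
    }
    counts <- mirna_count_matrix(known, novel, res$libraries)
    totals <- vapply(res$libraries, function(l) l$total_clean_reads, 0L)
    rptm <- normalize_rptm(counts, totals, cfg$quantify$scale_factor)
    expr <- select_expressed(rptm, cfg$quantify$min_rptm)
    res$rptm <- rptm
    res$expressed <- expr
    write_tsv(cbind(mirna_id = rownames(rptm), as.data.frame(rptm)),
              file.path(out_dir, "expression_matrix.tsv"))
    logf("quantify: %d miRNAs, %d above %g RPTM", nrow(rptm), nrow(expr),
         cfg$quantify$min_rptm)
  }

  if (st("cluster")) {
    if (is.null(expr)) stopf("stage 'cluster' requires stage 'quantify'")
    if (nrow(expr) >= cfg$cluster$k) {
      clus <- cluster_profiles(expr, k = cfg$cluster$k,
                               pseudocount = cfg$cluster$pseudocount,
                               distance = cfg$cluster$distance)
      res$clusters <- clus
      write_tsv(data.frame(mirna_id = names(clus$class),
                           cluster = clus$cluster, class = clus$class),
                file.path(out_dir, "clusters.tsv"))
      writeLines(clus$newick, file.path(out_dir, "dendrogram.nwk"))
      logf("cluster: %d profiles in %d classes", length(clus$class),
           length(unique(clus$class)))
    } else {
      logf("cluster: skipped, only %d expressed profiles", nrow(expr))
    }
  }

  hits <- NULL
  if (st("targets")) {
    mirnas <- setNames(res$sim$genome$loci$mature_seq,
                       res$sim$genome$loci$locus_id)
    hits <- scan_transcripts(mirnas, res$sim$validation$transcripts,
                             max_expectation = cfg$targets$max_expectation,
                             scheme = cfg$targets$scheme,
                             max_gaps = cfg$targets$max_gaps)
    res$target_hits <- hits
    res$target_summary <- target_summary(hits, names(mirnas))
    write_tsv(hits, file.path(out_dir, "targets.tsv"))
    logf("targets: %d hits, mean %.1f targets/miRNA", nrow(hits),
         res$target_summary$mean_targets_per_mirna)
  }

  if (st("race")) {
    if (is.null(hits)) stopf("stage 'race' requires stage 'targets'")
    val <- res$sim$validation
    maps <- list()
    for (i in seq_len(nrow(val$targets))) {
      tg <- val$targets[i, ]
      site_hits <- hits[hits$transcript_id == tg$target_id &
                          hits$mirna_id == tg$mirna_id, , drop = FALSE]
      if (nrow(site_hits) == 0L) next
      site <- site_hits[which.min(site_hits$expectation), ]
      cm <- map_cleavage(
        val$race_clones[val$race_clones$target_id == tg$target_id, ],
        target_len = tg$transcript_length,
        mirna_len = nchar(tg$mirna_seq), site = site,
        flank = cfg$race$flank)
      maps[[tg$target_id]] <- cbind(target_id = tg$target_id,
                                    mirna_id = tg$mirna_id, cm$positions,
                                    canonical_fraction = cm$canonical_fraction)
    }
    res$cleavage_maps <- maps
    if (length(maps)) {
      write_tsv(do.call(rbind, maps), file.path(out_dir, "cleavage_maps.tsv"))
    }
    logf("race: %d targets mapped", length(maps))
  }

  if (st("qpcr")) {
    val <- res$sim$validation
    calib <- cfg$qpcr$calibrator
    if (is.null(calib)) calib <- unique(val$qpcr_ct$sample)[1]
    dd <- ddct(val$qpcr_ct, val$reference_gene, calib)
    res$relative_expression <- dd
    write_tsv(dd$summary, file.path(out_dir, "relative_expression.tsv"))
    # miRNA/target anti-correlation over the four libraries
    cors <- list()
    if (!is.null(res$rptm)) {
      # novel calls carry fresh identifiers; match profiles by mature seq
      seq_of_row <- setNames(rownames(res$rptm), rownames(res$rptm))
      if (!is.null(res$novel) && nrow(res$novel$calls)) {
        seq_of_row[res$novel$calls$mirna_id] <- res$novel$calls$mature_seq
      }
      known_seqs <- vapply(res$known$calls, function(x) x$canonical, "")
      seq_of_row[names(known_seqs)] <- known_seqs
      for (i in seq_len(nrow(val$targets))) {
        tg <- val$targets[i, ]
        row <- if (tg$mirna_id %in% rownames(res$rptm)) tg$mirna_id else
          rownames(res$rptm)[match(tg$mirna_seq, seq_of_row)]
        if (is.na(row)) next
        mp <- res$rptm[row, ]
        tp <- dd$summary$rel_expr[dd$summary$gene == tg$target_id]
        if (length(tp) != length(mp) || sd(mp) == 0) next
        cc <- correlate_profiles(mp, tp)
        cors[[length(cors) + 1L]] <- data.frame(
          mirna_id = tg$mirna_id, target_id = tg$target_id, r = cc$r,
          anti_correlated = cc$anti_correlated)
      }
    }
    if (length(cors)) {
      res$correlations <- do.call(rbind, cors)
      write_tsv(res$correlations, file.path(out_dir, "correlations.tsv"))
    }
    logf("qpcr: %d genes quantified, %d correlations",
         length(unique(dd$summary$gene)),
         if (is.null(res$correlations)) 0L else nrow(res$correlations))
  }

  logf("done")
  invisible(res)
}

# per-miRNA count matrix combining known calls and novel calls
mirna_count_matrix <- function(known, novel, libs) {
  labels <- vapply(libs, function(l) l$label, "")
  rows <- list()
  for (call in known$calls) {
    rows[[call$mirna_id]] <- call$totals[labels]
  }
  if (nrow(novel$calls)) {
    pooled <- merge_libraries(libs)
    for (i in seq_len(nrow(novel$calls))) {
      seqs <- c(novel$calls$mature_seq[i])
      idx <- match(seqs, rownames(pooled))
      idx <- idx[!is.na(idx)]
      rows[[novel$calls$mirna_id[i]]] <- if (length(idx)) {
        colSums(pooled[idx, , drop = FALSE])[labels]
      } else {
        setNames(numeric(length(labels)), labels)
      }
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- labels
  m
}

# GFF3 for novel calls: precursor + mature features, 1-based closed
write_novel_gff3 <- function(calls, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(calls))) {
    ca <- calls[i, ]
    lines <- c(lines,
      sprintf("%s\tfibermir\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s",
              ca$chrom, ca$prec_start + 1L, ca$prec_end, ca$strand,
              ca$mirna_id),
      sprintf("%s\tfibermir\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s.mature;Parent=%s",
              ca$chrom, ca$mature_start + 1L, ca$mature_end, ca$strand,
              ca$mirna_id, ca$mirna_id))
  }
  writeLines(lines, path)
  invisible(path)
}
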