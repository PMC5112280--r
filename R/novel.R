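# Novel miRNA prediction: seed candidate loci from mapped read stacks, fold
# flanking windows, and apply hairpin criteria (duplex quality, asymmetric
# bulges, read dominance, MFE, MFEI) to call novel miRNAs.

#' Hairpin evaluation thresholds
#'
#' Defaults follow community gold criteria for plant miRNA annotation; the
#' MFEI 0.85 cutoff is recorded as a flag, not a hard filter, since genuine
#' miRNAs below it are routinely retained.
#'
#' @param max_unpaired_mature maximum unpaired mature bases in the hairpin.
#' @param max_duplex_mismatch maximum mismatched (symmetric-loop) bases in
#'   the mature/star duplex.
#' @param max_asym_bulges maximum asymmetric bulges in the duplex region.
#' @param min_dominance minimum fraction of precursor-mapped reads falling
#'   on the mature/star (+/- 2 nt) footprint.
#' @param mfe_max maximum (i.e. least negative) MFE in kcal/mol.
#' @param mfei_flag MFEI level above which the candidate is flagged as
#'   miRNA-like.
#' @return named list of thresholds.
#' @export
novel_thresholds <- function(max_unpaired_mature = 4L,
                             max_duplex_mismatch = 4L,
                             max_asym_bulges = 2L,
                             min_dominance = 0.8,
                             mfe_max = -18,
                             mfei_flag = 0.85) {
  list(max_unpaired_mature = max_unpaired_mature,
       max_duplex_mismatch = max_duplex_mismatch,
       max_asym_bulges = max_asym_bulges,
       min_dominance = min_dominance,
       mfe_max = mfe_max,
       mfei_flag = mfei_flag)
}

#' Walk the mature/star duplex of a folded precursor
#'
#' Given the pair table of a hairpin and the mature position within it,
#' determines the mature arm, the star span (with a 2-nt 3' overhang by
#' Dicer convention), and counts unpaired mature bases, duplex mismatches
#' (maximal unpaired runs with an equal number of unpaired bases on the
#' opposite strand contribute their run length) and asymmetric bulges
#' (maximal unpaired runs with unequal opposite-strand contributions count
#' once per run; this includes strand-exclusive bulges).
#'
#' @param pt integer pair table from [pair_table()].
#' @param mature_start,mature_end 1-based closed mature span within the
#'   precursor.
#' @param star_overhang 3' overhang applied to the inferred star span.
#' @return list: `arm` ("5p"/"3p"), `crosses_loop`, `unpaired_mature`,
#'   `duplex_mismatches`, `asymmetric_bulges`, `star_start`, `star_end`
#'   (1-based closed), `n_paired`.
#' @export
duplex_features <- function(pt, mature_start, mature_end, star_overhang = 2L) {
  n <- length(pt)
  if (mature_start < 1L || mature_end > n || mature_start > mature_end) {
    stopf("mature span [%d, %d] outside precursor of length %d",
          mature_start, mature_end, n)
  }
  span <- mature_start:mature_end
  partners <- pt[span]
  paired <- partners > 0L
  res <- list(arm = NA_character_, crosses_loop = FALSE,
              unpaired_mature = sum(!paired),
              duplex_mismatches = 0L, asymmetric_bulges = 0L,
              star_start = NA_integer_, star_end = NA_integer_,
              n_paired = sum(paired))
  if (!any(paired)) {
    res$crosses_loop <- TRUE  # degenerate: no pairing at all
    res$duplex_mismatches <- res$unpaired_mature
    return(res)
  }
  p <- partners[paired]
  if (all(p > mature_end)) {
    res$arm <- "5p"
  } else if (all(p < mature_start)) {
    res$arm <- "3p"
  } else {
    res$crosses_loop <- TRUE
    return(res)
  }
  # star span from partners; 3' end of the star (the side pairing the
  # mature 5' end) carries the overhang
  res$star_start <- min(p)
  res$star_end <- min(n, max(p) + star_overhang)

  # walk maximal unpaired runs between consecutive paired mature bases
  idx_paired <- span[paired]
  mm <- 0L
  bulges <- 0L
  for (k in seq_len(length(idx_paired) - 1L)) {
    i1 <- idx_paired[k]
    i2 <- idx_paired[k + 1L]
    gap_m <- i2 - i1 - 1L                  # unpaired mature bases in between
    gap_s <- abs(pt[i1] - pt[i2]) - 1L     # unpaired star bases opposite
    if (gap_m == 0L && gap_s == 0L) next
    if (gap_m == gap_s) {
      mm <- mm + gap_m                     # symmetric internal loop
    } else {
      bulges <- bulges + 1L                # asymmetric bulge (incl. 1-sided)
    }
  }
  # terminal unpaired mature bases have no defined opposite run; they count
  # as duplex mismatches of unknown pairing, never as bulges
  lead <- idx_paired[1] - mature_start
  trail <- mature_end - idx_paired[length(idx_paired)]
  res$duplex_mismatches <- mm + lead + trail
  res$asymmetric_bulges <- bulges
  res
}

#' Seed candidate precursor windows from mapped read stacks
#'
#' Overlapping alignments of eligible reads (not contaminant, not assigned
#' to a known miRNA, not multi-mapping) are clustered per chromosome and
#' strand with a merge gap, and for each cluster the modal (highest-count)
#' read becomes the prospective mature.  Two flanking windows are emitted
#' per cluster so the mature may sit on either hairpin arm.
#'
#' @param hits data.frame of alignments with columns `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `count`, `sequence`.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param min_stack minimum summed read count for a cluster.
#' @param window flank length added on the far side of the mature.
#' @param near_flank flank on the mature-proximal side.
#' @param merge_gap maximum gap between alignments merged into a cluster.
#' @param min_read_count minimum count for a read to take part in
#'   clustering; singleton background fragments otherwise chain distinct
#'   loci together on deeply covered genomes (they still contribute to
#'   dominance, just not to seeding).
#' @return data.frame of candidate windows: `cluster`, `chrom`, `strand`,
#'   `win_start`, `win_end` (0-based half-open), `mature_start`,
#'   `mature_end`, `mature_seq`, `stack_count`.
#' @export
seed_loci <- function(hits, chrom_lengths, min_stack = 5L, window = 250L,
                      near_flank = 20L, merge_gap = 10L,
                      min_read_count = 2L) {
  hits <- hits[hits$count >= min_read_count, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(cluster = integer(0), chrom = character(0),
                      strand = character(0), win_start = integer(0),
                      win_end = integer(0), mature_start = integer(0),
                      mature_end = integer(0), mature_seq = character(0),
                      stack_count = numeric(0)))
  }
  out <- list()
  cl_id <- 0L
  for (key in unique(paste(hits$chrom, hits$strand))) {
    sub <- hits[paste(hits$chrom, hits$strand) == key, , drop = FALSE]
    ir <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
    red <- IRanges::reduce(ir, min.gapwidth = merge_gap + 1L)
    ov <- IRanges::findOverlaps(ir, red)
    for (j in seq_along(red)) {
      members <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == j]
      total <- sum(sub$count[members])
      if (total < min_stack) next
      best <- members[order(-sub$count[members], sub$start[members])][1]
      m_start <- sub$start[best]
      m_end <- sub$end[best]
      cl_id <- cl_id + 1L
      clen <- chrom_lengths[[sub$chrom[1]]]
      for (side in c("left", "right")) {
        ws <- if (side == "left") m_start - window else m_start - near_flank
        we <- if (side == "left") m_end + near_flank else m_end + window
        out[[length(out) + 1L]] <- data.frame(
          cluster = cl_id, chrom = sub$chrom[1], strand = sub$strand[1],
          win_start = max(0L, as.integer(ws)),
          win_end = min(clen, as.integer(we)),
          mature_start = m_start, mature_end = m_end,
          mature_seq = sub$sequence[best], stack_count = total,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(seed_loci(hits[0, , drop = FALSE], chrom_lengths))
  }
  rownames(res) <- NULL
  res
}

#' Evaluate a folded precursor candidate against hairpin criteria
#'
#' Applies the plant miRNA annotation criteria: (1) mature on a single arm
#' with few unpaired bases, (2) limited duplex mismatches against the star,
#' (3) at most two asymmetric bulges in the duplex, (4) read dominance of
#' the mature/star footprint, (5) MFE at most `mfe_max`; the MFEI is
#' computed and flagged against 0.85 but is not a hard filter.
#'
#' @param precursor_seq precursor sequence (DNA alphabet).
#' @param structure dot-bracket structure of `precursor_seq`.
#' @param mfe minimum free energy (kcal/mol).
#' @param mature_offset 0-based offset of the mature within the precursor.
#' @param mature_len mature length (nt).
#' @param locus_reads optional data.frame of reads overlapping the
#'   precursor (columns `offset` 0-based within precursor, `length`,
#'   `count`) for dominance; `NULL` skips the dominance criterion.
#' @param thresholds from [novel_thresholds()].
#' @param star_overhang Dicer-style star 3' overhang (nt).
#' @return one-row data.frame (a HairpinCandidate): sequence/structure
#'   metrics, duplex statistics, `dominance`, `verdict` and
#'   `failed_criteria`.
#' @export
evaluate_hairpin <- function(precursor_seq, structure, mfe, mature_offset,
                             mature_len, locus_reads = NULL,
                             thresholds = novel_thresholds(),
                             star_overhang = 2L) {
  n <- nchar(precursor_seq)
  if (nchar(structure) != n) stopf("structure length != precursor length")
  m_start <- mature_offset + 1L
  m_end <- mature_offset + mature_len
  if (m_start < 1L || m_end > n) stopf("mature not within precursor")
  pt <- pair_table(structure)
  feats <- duplex_features(pt, m_start, m_end, star_overhang)
  gc <- gc_percent(precursor_seq)
  mfei_val <- mfei(mfe, n, gc)

  dominance <- NA_real_
  if (!is.null(locus_reads) && nrow(locus_reads) > 0L) {
    fp <- matrix(c(m_start - 2L, m_end + 2L), ncol = 2)
    if (!is.na(feats$star_start)) {
      fp <- rbind(fp, c(feats$star_start - 2L, feats$star_end + 2L))
    }
    rs <- locus_reads$offset + 1L
    re <- locus_reads$offset + locus_reads$length
    on_fp <- rep(FALSE, nrow(locus_reads))
    for (r in seq_len(nrow(fp))) {
      on_fp <- on_fp | (rs >= fp[r, 1] & re <= fp[r, 2])
    }
    dominance <- sum(locus_reads$count[on_fp]) / sum(locus_reads$count)
  }

  failed <- character(0)
  if (feats$crosses_loop ||
      feats$unpaired_mature > thresholds$max_unpaired_mature) {
    failed <- c(failed, "mature_arm")
  }
  if (feats$duplex_mismatches > thresholds$max_duplex_mismatch) {
    failed <- c(failed, "duplex_mismatches")
  }
  if (feats$asymmetric_bulges > thresholds$max_asym_bulges) {
    failed <- c(failed, "asymmetric_bulges")
  }
  if (!is.na(dominance) && dominance < thresholds$min_dominance) {
    failed <- c(failed, "dominance")
  }
  if (mfe > thresholds$mfe_max) {
    failed <- c(failed, "mfe")
  }
  star_seq <- if (!is.na(feats$star_start)) {
    substr(precursor_seq, feats$star_start, feats$star_end)
  } else {
    NA_character_
  }
  data.frame(
    precursor_seq = precursor_seq, structure = structure, mfe = mfe,
    length = n, gc_percent = gc, mfei = mfei_val,
    mfei_flag = !is.na(mfei_val) && mfei_val >= thresholds$mfei_flag,
    mature_seq = substr(precursor_seq, m_start, m_end),
    mature_arm = feats$arm, star_seq = star_seq,
    unpaired_mature = feats$unpaired_mature,
    duplex_mismatches = feats$duplex_mismatches,
    asymmetric_bulges = feats$asymmetric_bulges,
    dominance = dominance,
    verdict = length(failed) == 0L,
    failed_criteria = paste(failed, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Predict novel miRNAs from annotated libraries
#'
#' Orchestrates seeding, folding and hairpin evaluation.  Reads classified
#' as contaminants or assigned to known miRNAs are excluded; remaining
#' unique reads are mapped, stacked into clusters, and every cluster's two
#' flanking windows are folded and evaluated.  A cluster passing on both
#' windows keeps the lower-MFE precursor.
#'
#' @param counts sequence-by-library count matrix of eligible reads (e.g.
#'   [assign_known()]`$unassigned`).
#' @param genome genome as for [map_to_genome()].
#' @param thresholds from [novel_thresholds()].
#' @param min_stack,window,merge_gap seeding parameters ([seed_loci()]).
#' @param max_hits multi-mapper threshold.
#' @param backend folding backend ([fold_rna()]).
#' @param mature_length_range lengths accepted for a prospective mature.
#' @param exclude_hairpins optional named character vector of known
#'   precursor sequences; reads occurring within them (e.g. star or loop
#'   fragments of known miRNAs) are removed before seeding.
#' @param precursor_pad padding kept around the mature/star duplex when the
#'   folded window is trimmed to the hairpin precursor.
#' @return list with `calls` (passing HairpinCandidate rows plus locus
#'   coordinates and per-library read support) and `candidates` (all
#'   evaluated windows).
#' @export
predict_novel <- function(counts, genome, thresholds = novel_thresholds(),
                          min_stack = 5L, window = 250L, merge_gap = 10L,
                          max_hits = 20L, backend = "auto",
                          mature_length_range = c(19L, 24L),
                          exclude_hairpins = NULL, precursor_pad = 10L,
                          min_read_count = 2L) {
  genome <- load_genome(genome)
  chrom_lengths <- vapply(genome, nchar, 0L)
  if (!is.null(exclude_hairpins) && length(exclude_hairpins) &&
      nrow(counts)) {
    inhp <- subsequence_hits(rownames(counts), exclude_hairpins)
    counts <- counts[!inhp, , drop = FALSE]
  }
  lib <- new_read_library("pool", rownames(counts), rowSums(counts))
  lib <- map_to_genome(lib, genome, max_mismatch = 0L, max_hits = max_hits)
  hits <- lib$genome_hits
  eligible <- which(!lib$multi_mapper)
  hits <- hits[hits$read %in% eligible, , drop = FALSE]
  hits$count <- lib$counts[hits$read]
  hits$sequence <- lib$sequences[hits$read]
  seeds <- seed_loci(hits, chrom_lengths, min_stack = min_stack,
                     window = window, merge_gap = merge_gap,
                     min_read_count = min_read_count)
  len_ok <- nchar(seeds$mature_seq) >= mature_length_range[1] &
    nchar(seeds$mature_seq) <= mature_length_range[2]
  seeds <- seeds[len_ok, , drop = FALSE]
  if (nrow(seeds) == 0L) {
    return(list(calls = cbind(seeds[0, ], evaluate_hairpin("ACGT", "....",
                                                           0, 0, 4)[0, ]),
                candidates = seeds))
  }
  # pass 1: fold the full windows, locate the star arm, and trim each
  # window to the hairpin precursor (duplex span + padding); pass 2: refold
  # the trimmed precursors and evaluate the criteria on those
  win_seq <- character(nrow(seeds))
  mat_off <- integer(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    s <- substr(genome[[seeds$chrom[i]]], seeds$win_start[i] + 1L,
                seeds$win_end[i])
    win_seq[i] <- if (seeds$strand[i] == "-") revcomp(s) else s
    mat_off[i] <- if (seeds$strand[i] == "+") {
      seeds$mature_start[i] - seeds$win_start[i]
    } else {
      seeds$win_end[i] - seeds$mature_end[i]
    }
  }
  folded1 <- fold_rna(win_seq, backend = backend)
  trim_start <- integer(nrow(seeds))   # 0-based within window
  prec_seq <- character(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    mlen <- nchar(seeds$mature_seq[i])
    wlen <- nchar(win_seq[i])
    feats <- duplex_features(pair_table(folded1$structure[i]),
                             mat_off[i] + 1L, mat_off[i] + mlen)
    if (!is.na(feats$star_start)) {
      lo <- max(1L, min(mat_off[i] + 1L, feats$star_start) - precursor_pad)
      hi <- min(wlen, max(mat_off[i] + mlen, feats$star_end) + precursor_pad)
    } else {
      lo <- 1L
      hi <- wlen
    }
    trim_start[i] <- lo - 1L
    prec_seq[i] <- substr(win_seq[i], lo, hi)
  }
  folded <- fold_rna(prec_seq, backend = backend)
  evals <- vector("list", nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    off <- mat_off[i] - trim_start[i]
    plen <- nchar(prec_seq[i])
    reads_here <- hits[hits$chrom == seeds$chrom[i] &
                         hits$strand == seeds$strand[i] &
                         hits$start < seeds$win_end[i] &
                         hits$end > seeds$win_start[i], , drop = FALSE]
    woff <- if (seeds$strand[i] == "+") {
      reads_here$start - seeds$win_start[i]
    } else {
      seeds$win_end[i] - reads_here$end
    }
    locus_reads <- data.frame(
      offset = woff - trim_start[i],
      length = reads_here$end - reads_here$start,
      count = reads_here$count
    )
    # dominance is judged over reads on the trimmed precursor
    locus_reads <- locus_reads[locus_reads$offset + locus_reads$length > 0 &
                                 locus_reads$offset < plen, , drop = FALSE]
    evals[[i]] <- evaluate_hairpin(
      folded$sequence[i], folded$structure[i], folded$mfe[i],
      mature_offset = off, mature_len = nchar(seeds$mature_seq[i]),
      locus_reads = locus_reads, thresholds = thresholds
    )
  }
  candidates <- cbind(seeds, do.call(rbind, evals),
                      fold_backend = folded$backend)
  # genomic coordinates of the trimmed precursor
  candidates$prec_start <- ifelse(
    seeds$strand == "+", seeds$win_start + trim_start,
    seeds$win_end - trim_start - nchar(prec_seq))
  candidates$prec_end <- candidates$prec_start + nchar(prec_seq)
  # deduplicate: one call per cluster, lower MFE wins among passing windows
  pass <- candidates[candidates$verdict, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(pass)), pass$cluster),
                        function(ix) ix[order(pass$mfe[ix])][1]))
  calls <- pass[sort(keep), , drop = FALSE]
  # a hairpin read on the opposite strand (e.g. the star arm) can seed the
  # same locus twice; collapse overlapping precursors, lower MFE wins
  if (nrow(calls) > 1L) {
    keep <- rep(TRUE, nrow(calls))
    o <- order(calls$mfe)
    taken <- list()
    for (i in o) {
      iv <- c(calls$prec_start[i], calls$prec_end[i])
      clash <- any(vapply(taken, function(tv) {
        tv$chrom == calls$chrom[i] && iv[1] < tv$e && iv[2] > tv$s
      }, TRUE))
      if (clash) {
        keep[i] <- FALSE
      } else {
        taken[[length(taken) + 1L]] <- list(chrom = calls$chrom[i],
                                            s = iv[1], e = iv[2])
      }
    }
    calls <- calls[keep, , drop = FALSE]
  }
  if (nrow(calls)) {
    calls$mirna_id <- sprintf("nov-%03d", seq_len(nrow(calls)))
  } else {
    calls$mirna_id <- character(0)
  }
  rownames(calls) <- NULL
  list(calls = calls, candidates = candidates)
}

#' Cross-tabulate novel miRNA calls by 5' nucleotide and length
#'
#' Reproduces the classical first-nucleotide-by-length summary of novel
#' miRNA sets, with row/column/grand totals and the 5' nucleotide
#' percentages to one decimal.
#'
#' @param calls data.frame with a `mature_seq` column, or one with
#'   `first_nt` (A/U/C/G) and `length` columns.
#' @return list with `table` (matrix incl. `Total` row/column) and
#'   `first_nt_percent` (named numeric, one decimal).
#' @export
novel_summary <- function(calls) {
  if (nrow(calls) == 0L) {
    tab <- matrix(0L, nrow = 5, ncol = 1,
                  dimnames = list(c("A", "U", "C", "G", "Total"), "Total"))
    return(list(table = tab,
                first_nt_percent = setNames(numeric(4),
                                            c("A", "U", "C", "G"))))
  }
  if ("mature_seq" %in% names(calls)) {
    first <- substr(as_rna(calls$mature_seq), 1L, 1L)
    len <- nchar(calls$mature_seq)
  } else {
    first <- as_rna(calls$first_nt)
    len <- calls$length
  }
  first <- factor(first, levels = c("A", "U", "C", "G"))
  lengths_seen <- sort(unique(len))
  tab <- table(first, factor(len, levels = lengths_seen))
  tab <- cbind(tab, Total = rowSums(tab))
  tab <- rbind(tab, Total = colSums(tab))
  storage.mode(tab) <- "integer"
  pct <- round_half_up(100 * tab[c("A", "U", "C", "G"), "Total"] /
                         tab["Total", "Total"], 1)
  list(table = tab, first_nt_percent = pct)
}
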