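# Read annotation: contaminant classification against per-class reference
# sets and exact genome mapping, feeding the class-distribution report.

CONTAMINANT_CLASSES <- c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat")

#' Classify reads against contaminant reference sets
#'
#' Each unique read is labelled with the first reference class (priority
#' order as given, by default rRNA > tRNA > snRNA > snoRNA > repeat) that
#' contains it as a subsequence with at most `max_mismatch` substitutions;
#' unmatched reads are labelled `"none"`.
#'
#' @param lib a `ReadLibrary`.
#' @param refs_by_class named list of reference sequence sets (character
#'   vectors, `DNAStringSet`s, or FASTA paths), in priority order.
#' @param max_mismatch substitutions tolerated (0 = exact subsequence).
#' @return the library with an `annotation_class` factor (levels: the
#'   classes plus `"none"`) parallel to `sequences`.
#' @export
classify_contaminants <- function(lib, refs_by_class, max_mismatch = 0L) {
  stopifnot(inherits(lib, "ReadLibrary"))
  if (length(refs_by_class) == 0L) {
    stopf("at least one contaminant reference class is required")
  }
  classes <- names(refs_by_class)
  if (is.null(classes) || any(!nzchar(classes))) {
    stopf("refs_by_class must be a named list")
  }
  refs_by_class <- lapply(refs_by_class, function(r) {
    if (is.character(r) && length(r) == 1L && file.exists(r)) r <- read_fasta(r)
    as.character(r)
  })
  empty <- vapply(refs_by_class, length, 0L) == 0L
  if (any(empty)) {
    stopf("empty reference set for class(es): %s",
          paste(classes[empty], collapse = ", "))
  }
  lib$annotation_class <- classify_sequences(lib$sequences, refs_by_class,
                                             max_mismatch)
  lib
}

# factor of contaminant classes (priority order = list order) for a
# character vector of sequences; one PDict per read width serves all classes
classify_sequences <- function(seqs, refs_by_class, max_mismatch = 0L) {
  classes <- names(refs_by_class)
  ann <- rep("none", length(seqs))
  if (max_mismatch == 0L) {
    subjects <- lapply(refs_by_class, Biostrings::DNAStringSet)
    for (w in unique(nchar(seqs))) {
      idx <- which(nchar(seqs) == w)
      pd <- Biostrings::PDict(seqs[idx])
      open <- rep(TRUE, length(idx))
      for (cls in classes) {
        if (!any(open)) break
        hit <- rowSums(Biostrings::vcountPDict(pd, subjects[[cls]])) > 0L
        ann[idx[open & hit]] <- cls
        open <- open & !hit
      }
    }
  } else {
    for (cls in classes) {
      todo <- which(ann == "none")
      if (length(todo) == 0L) break
      hit <- subsequence_hits(seqs[todo], refs_by_class[[cls]], max_mismatch)
      ann[todo[hit]] <- cls
    }
  }
  factor(ann, levels = c(classes, "none"))
}

# Which reads occur as a (sense-strand) subsequence of any reference, with
# at most max_mismatch substitutions.
subsequence_hits <- function(reads, refs, max_mismatch = 0L) {
  if (length(reads) == 0L) return(logical(0))
  subj <- Biostrings::DNAStringSet(refs)
  hit <- logical(length(reads))
  if (max_mismatch == 0L) {
    for (w in unique(nchar(reads))) {
      idx <- which(nchar(reads) == w)
      pd <- Biostrings::PDict(reads[idx])
      counts <- rowSums(Biostrings::vcountPDict(pd, subj))
      hit[idx] <- counts > 0L
    }
  } else {
    for (i in seq_along(reads)) {
      n <- Biostrings::vcountPattern(reads[i], subj,
                                     max.mismatch = max_mismatch)
      hit[i] <- sum(n) > 0L
    }
  }
  hit
}

#' Map library reads to a genome
#'
#' Records every occurrence of each unique read on both genome strands with
#' at most `max_mismatch` substitutions.  Reads with more than `max_hits`
#' occurrences are flagged as multi-mappers: they still count as
#' genome-matched but are excluded from novel-locus seeding.
#'
#' @param lib a `ReadLibrary`.
#' @param genome named character vector of chromosome sequences (or a
#'   `DNAStringSet`, or a FASTA path).
#' @param max_mismatch substitutions tolerated (0 = exact, the small-RNA
#'   standard).
#' @param max_hits multi-mapper threshold.
#' @return the library with `genome_hits` (data.frame: `read` index into
#'   `sequences`, `chrom`, `start` 0-based, `end` exclusive, `strand`,
#'   `mismatches`), plus logical vectors `genome_matched` and
#'   `multi_mapper`.
#' @export
map_to_genome <- function(lib, genome, max_mismatch = 0L, max_hits = 20L) {
  stopifnot(inherits(lib, "ReadLibrary"))
  genome <- load_genome(genome)
  hits <- list()
  for (chrom in names(genome)) {
    subj <- Biostrings::DNAString(genome[[chrom]])
    for (strand in c("+", "-")) {
      pats <- if (strand == "+") lib$sequences else revcomp(lib$sequences)
      h <- find_occurrences(pats, subj, max_mismatch)
      if (nrow(h)) {
        h$chrom <- chrom
        h$strand <- strand
        hits[[length(hits) + 1L]] <- h
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(read = integer(0), start = integer(0), end = integer(0),
               mismatches = integer(0), chrom = character(0),
               strand = character(0))
  hits <- hits[order(hits$read, hits$chrom, hits$start, hits$strand),
               c("read", "chrom", "start", "end", "strand", "mismatches")]
  rownames(hits) <- NULL
  nh <- tabulate(hits$read, nbins = length(lib$sequences))
  lib$genome_hits <- hits
  lib$genome_matched <- nh > 0L
  lib$multi_mapper <- nh > max_hits
  lib
}

load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_fasta(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (is.null(names(genome))) names(genome) <- paste0("chr", seq_along(genome))
  as.list(genome)
}

# All occurrences of each pattern in one subject strand; PDict per width
# group when exact, per-pattern matchPattern otherwise.
find_occurrences <- function(pats, subj, max_mismatch) {
  out <- list()
  if (max_mismatch == 0L) {
    for (w in unique(nchar(pats))) {
      idx <- which(nchar(pats) == w)
      pd <- Biostrings::PDict(pats[idx])
      m <- Biostrings::matchPDict(pd, subj)
      nm <- S4Vectors::elementNROWS(m)
      if (sum(nm) == 0L) next
      ir <- unlist(m)
      out[[length(out) + 1L]] <- data.frame(
        read = rep(idx, nm),
        start = BiocGenerics::start(ir) - 1L,
        end = BiocGenerics::end(ir),
        mismatches = 0L
      )
    }
  } else {
    for (i in seq_along(pats)) {
      m <- Biostrings::matchPattern(pats[i], subj,
                                    max.mismatch = max_mismatch)
      if (length(m) == 0L) next
      mm <- Biostrings::neditAt(Biostrings::DNAString(pats[i]), subj,
                                at = BiocGenerics::start(m))
      out[[length(out) + 1L]] <- data.frame(
        read = i,
        start = BiocGenerics::start(m) - 1L,
        end = BiocGenerics::end(m),
        mismatches = as.integer(mm)
      )
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(read = integer(0), start = integer(0), end = integer(0),
               mismatches = integer(0))
}

#' Class-distribution table across libraries
#'
#' Summarizes each annotated library the way small-RNA surveys report read
#' classes: clean reads (100%), genome-matched, each contaminant class, and
#' reads with no annotation.  Reads are partitioned: contaminant classes
#' take precedence, remaining reads are genome-matched or unannotated.
#'
#' @param libs list of libraries processed by both
#'   [classify_contaminants()] and [map_to_genome()].
#' @return data.frame in long form: `library`, `class`, `count`, `percent`
#'   (of clean reads, two decimals, half-up rounding).
#' @export
class_distribution_table <- function(libs) {
  rows <- lapply(libs, function(lib) {
    stopifnot(!is.null(lib$annotation_class), !is.null(lib$genome_matched))
    cls <- as.character(lib$annotation_class)
    is_cont <- cls != "none"
    counts <- c(
      `Clean reads` = lib$total_clean_reads,
      `Match to genome` = sum(lib$counts[!is_cont & lib$genome_matched]),
      vapply(levels(lib$annotation_class)[levels(lib$annotation_class) !=
                                            "none"],
             function(k) sum(lib$counts[cls == k]), 0L),
      `No annotation` = sum(lib$counts[!is_cont & !lib$genome_matched])
    )
    data.frame(library = lib$label, class = names(counts),
               count = as.integer(counts), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  clean <- out$count[out$class == "Clean reads"][
    match(out$library, unique(out$library))]
  out$percent <- class_percent(out$count, clean)
  out
}

#' Percentage-of-clean-reads arithmetic used by the class table
#'
#' @param count read counts per class.
#' @param clean_reads the library's clean-read total (recycled).
#' @return percentages of clean reads, two decimals, half-up rounding.
#' @examples
#' class_percent(2338626, 7334102)  # 31.89
#' @export
class_percent <- function(count, clean_reads) {
  if (any(clean_reads <= 0)) stopf("clean_reads must be positive")
  round_half_up(100 * count / clean_reads, 2)
}
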