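# Raw FASTQ -> collapsed clean-read libraries.
#
# A ReadLibrary holds the collapsed analysis set of one sequencing library:
# unique insert sequences with their read counts, the library label (DPA
# stage), and discard tallies from cleaning.

#' Construct a collapsed read library
#'
#' @param label library name (e.g. the DPA stage).
#' @param sequences unique read sequences (DNA alphabet).
#' @param counts read count per sequence.
#' @param discards named tally of discarded reads by reason.
#' @param n_input number of raw reads the library was built from.
#' @return a `ReadLibrary` object (sequences sorted, counts aligned).
#' @export
new_read_library <- function(label, sequences, counts, discards = integer(0),
                             n_input = sum(counts)) {
  sequences <- as.character(sequences)
  stopifnot(length(sequences) == length(counts))
  o <- order(sequences)
  lib <- list(
    label = label,
    sequences = sequences[o],
    counts = as.integer(counts[o]),
    total_clean_reads = sum(as.integer(counts)),
    discards = discards,
    n_input = n_input
  )
  class(lib) <- "ReadLibrary"
  lib
}

#' @export
print.ReadLibrary <- function(x, ...) {
  cat(sprintf("ReadLibrary '%s': %d unique sequences, %d clean reads\n",
              x$label, length(x$sequences), x$total_clean_reads))
  if (length(x$discards)) {
    cat("  discarded:",
        paste(sprintf("%s=%d", names(x$discards), x$discards), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Trim a 3' adaptor from read sequences
#'
#' Locates the adaptor by the leftmost occurrence of a prefix of at least
#' `min_overlap` bases with at most `max_mismatch` substitutions, and
#' removes everything from that point on.  Reads without a located adaptor
#' are returned unchanged, so trimming is idempotent.
#'
#' @param seqs character vector of read sequences.
#' @param adaptor_3p the 3' adaptor sequence (non-empty).
#' @param min_overlap minimum adaptor prefix length that must be present.
#' @param max_mismatch substitutions tolerated in the overlap.
#' @return list with `trimmed` (character) and `found` (logical).
#' @export
trim_adaptor <- function(seqs, adaptor_3p, min_overlap = 8L,
                         max_mismatch = 1L) {
  if (!nzchar(adaptor_3p)) stopf("adaptor_3p must be non-empty")
  adaptor_3p <- as_dna(adaptor_3p)
  min_overlap <- min(min_overlap, nchar(adaptor_3p))
  seed <- substr(adaptor_3p, 1L, min_overlap)
  pos <- as.integer(regexpr(seed, seqs, fixed = TRUE))
  # exact-seed fast path misses matches whose mismatch falls inside the
  # seed; rescue those with a per-read scan
  miss <- which(pos < 0L & nchar(seqs) >= min_overlap)
  if (max_mismatch > 0L && length(miss)) {
    pos[miss] <- vapply(seqs[miss], scan_adaptor_1, 0L,
                        adaptor = adaptor_3p, min_overlap = min_overlap,
                        max_mismatch = max_mismatch, USE.NAMES = FALSE)
  }
  found <- pos > 0L
  trimmed <- seqs
  trimmed[found] <- substr(seqs[found], 1L, pos[found] - 1L)
  list(trimmed = trimmed, found = found)
}

scan_adaptor_1 <- function(seq, adaptor, min_overlap, max_mismatch) {
  n <- nchar(seq)
  ab <- utf8ToInt(adaptor)
  sb <- utf8ToInt(seq)
  for (s in seq_len(n - min_overlap + 1L)) {
    ov <- min(n - s + 1L, length(ab))
    if (sum(sb[s:(s + ov - 1L)] != ab[seq_len(ov)]) <= max_mismatch) {
      return(s)
    }
  }
  -1L
}

#' Clean and collapse a raw small-RNA FASTQ library
#'
#' Applies the standard small-RNA preprocessing cascade: minimum base
#' quality, no ambiguous bases, 3' adaptor located and trimmed (reads
#' without an adaptor are discarded as un-ligated), insert length inside
#' `[min_len, max_len]`.  Survivors are collapsed to unique sequences with
#' counts.  Cleaning bounds are configurable so a wider cleaning window
#' (e.g. 18--44 nt) can be followed by [subset_lengths()] for the analysis
#' set (18--28 nt).
#'
#' @param fastq path to a FASTQ file (Sanger qualities).
#' @param adaptor_3p 3' adaptor sequence.
#' @param min_len,max_len inclusive insert-length bounds.
#' @param min_qual minimum per-base Phred score.
#' @param min_overlap,max_adaptor_mismatch adaptor search parameters, see
#'   [trim_adaptor()].
#' @param label library label; defaults to the file name.
#' @return a `ReadLibrary` object.
#' @export
clean_reads <- function(fastq, adaptor_3p, min_len = 18L, max_len = 28L,
                        min_qual = 20L, min_overlap = 8L,
                        max_adaptor_mismatch = 1L, label = NULL) {
  if (is.null(label)) {
    label <- sub("\\.(fastq|fq)(\\.gz)?$", "", basename(fastq))
  }
  reads <- tryCatch(
    Biostrings::readDNAStringSet(fastq, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) stopf("malformed FASTQ '%s': %s", fastq,
                              conditionMessage(e))
  )
  seqs <- as.character(reads)
  quals <- as.character(S4Vectors::mcols(reads)$qualities)
  # per-read minimum Phred score; quality strings are highly repetitive so
  # decode unique strings only
  uq <- unique(quals)
  minq <- vapply(uq, function(q) min(utf8ToInt(q)) - 33L, 0L)
  ok_qual <- minq[match(quals, uq)] >= min_qual
  has_n <- grepl("N", seqs, fixed = TRUE)

  discards <- c(low_quality = 0L, contains_N = 0L, no_adaptor = 0L,
                too_short = 0L, too_long = 0L)
  keep <- ok_qual & !has_n
  discards["low_quality"] <- sum(!ok_qual)
  discards["contains_N"] <- sum(ok_qual & has_n)

  tr <- trim_adaptor(seqs[keep], adaptor_3p, min_overlap,
                     max_adaptor_mismatch)
  discards["no_adaptor"] <- sum(!tr$found)
  inserts <- tr$trimmed[tr$found]
  len <- nchar(inserts)
  discards["too_short"] <- sum(len < min_len)
  discards["too_long"] <- sum(len > max_len)
  inserts <- inserts[len >= min_len & len <= max_len]

  tab <- table(inserts)
  new_read_library(label, names(tab), as.integer(tab), discards,
                   n_input = length(seqs))
}

#' Restrict a library to an insert-length window
#'
#' @param lib a `ReadLibrary`.
#' @param min_len,max_len inclusive bounds of the analysis set.
#' @return a `ReadLibrary` containing only sequences within the bounds.
#' @export
subset_lengths <- function(lib, min_len = 18L, max_len = 28L) {
  stopifnot(inherits(lib, "ReadLibrary"))
  len <- nchar(lib$sequences)
  keep <- len >= min_len & len <= max_len
  new_read_library(lib$label, lib$sequences[keep], lib$counts[keep],
                   lib$discards, lib$n_input)
}

#' Read-length distribution of a library
#'
#' @param lib a `ReadLibrary`.
#' @return data.frame with `length`, `count` and `fraction` (summing to 1),
#'   plus an attribute `fraction_20_24` giving the aggregate 20--24 nt
#'   fraction, the canonical small-RNA size range.
#' @export
length_distribution <- function(lib) {
  stopifnot(inherits(lib, "ReadLibrary"))
  if (length(lib$sequences) == 0L) stopf("empty library '%s'", lib$label)
  len <- nchar(lib$sequences)
  counts <- vapply(split(lib$counts, len), sum, 0L)
  df <- data.frame(length = as.integer(names(counts)),
                   count = as.integer(counts))
  df <- df[order(df$length), , drop = FALSE]
  rownames(df) <- NULL
  df$fraction <- df$count / sum(df$count)
  attr(df, "fraction_20_24") <-
    sum(df$fraction[df$length >= 20L & df$length <= 24L])
  df
}

#' Expand a collapsed library back to a read multiset
#'
#' Inverse of collapsing; mainly used to verify count conservation.
#'
#' @param lib a `ReadLibrary`.
#' @return character vector with each sequence repeated by its count.
#' @export
expand_library <- function(lib) {
  rep(lib$sequences, lib$counts)
}
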