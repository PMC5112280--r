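# Shared low-level helpers.  Sequences are held as plain character vectors in
# the DNA alphabet (T, never U) everywhere inside the package; report writers
# convert to U where miRNA convention expects it.  Genomic coordinates are
# 0-based half-open internally and 1-based closed in GFF3/report output.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Convert between DNA and RNA alphabets
#'
#' @param x character vector of sequences.
#' @return `as_dna()` returns the uppercased sequence with U replaced by T;
#'   `as_rna()` replaces T by U.
#' @examples
#' as_dna("acgu")
#' as_rna("ACGT")
#' @export
as_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' @rdname as_dna
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

#' Reverse complement of DNA sequences
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  out <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' G/C content as a percentage
#'
#' @param x character vector of DNA/RNA sequences.
#' @return numeric vector, percent G+C in 0--100 (the convention under which
#'   the minimal folding free energy index is defined).
#' @export
gc_percent <- function(x) {
  s <- Biostrings::DNAStringSet(as_dna(x))
  gc <- Biostrings::letterFrequency(s, letters = c("G", "C"))
  unname(100 * rowSums(gc) / Biostrings::width(s))
}

# Round half away from zero (spreadsheet-style), used for all reported
# percentages; base round() is round-half-even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Random DNA sequences with a target G+C fraction
#'
#' Draws i.i.d. bases under the current RNG state, so sequences are
#' reproducible given a seed.
#'
#' @param n number of sequences.
#' @param len sequence length(s), recycled to `n`.
#' @param gc G+C fraction in 0--1.
#' @return character vector of `n` sequences.
#' @export
random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  len <- rep_len(len, n)
  chars <- sample(names(p), sum(len), replace = TRUE, prob = p)
  if (n == 0L) return(character(0))
  unname(vapply(split(chars, rep.int(seq_len(n), len)), paste, "",
                collapse = "")[as.character(seq_len(n))])
}

# Substitute k random positions with a different base.
mutate_seq <- function(seq, k) {
  if (k == 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), k)
  for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Parse a dot-bracket secondary structure into a pair table
#'
#' @param structure a single dot-bracket string (characters `(`, `)`, `.`).
#' @return integer vector `p` with `p[i]` the 1-based partner of base `i`,
#'   or 0 if unpaired.
#' @export
pair_table <- function(structure) {
  ch <- strsplit(structure, "", fixed = TRUE)[[1]]
  n <- length(ch)
  pt <- integer(n)
  stack <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      top <- top + 1L
      stack[top] <- i
    } else if (ch[i] == ")") {
      if (top == 0L) stopf("unbalanced structure string at position %d", i)
      j <- stack[top]
      top <- top - 1L
      pt[i] <- j
      pt[j] <- i
    } else if (ch[i] != ".") {
      stopf("unexpected character '%s' in structure string", ch[i])
    }
  }
  if (top != 0L) stopf("unbalanced structure string: %d unclosed pairs", top)
  pt
}

# Count character mismatches between equal-length strings (vectorized over x).
string_mismatches <- function(x, y) {
  stopifnot(length(y) == 1L)
  yb <- utf8ToInt(y)
  vapply(x, function(s) {
    sb <- utf8ToInt(s)
    if (length(sb) != length(yb)) stopf("length mismatch in comparison")
    sum(sb != yb)
  }, 0L, USE.NAMES = FALSE)
}

read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  setNames(as.character(s), names(s))
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
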